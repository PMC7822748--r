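test_that("pattern generation validates inputs and handles degenerate density", {
  expect_error(generatePattern("blob", 10), "star, array, lines")
  expect_error(generatePattern("star", -1), "positive")
  es <- generatePattern("array", 1e-9, seed = 1)
  expect_gte(nrow(es@positions), 1)
  lim <- es@fieldPx * es@pixelNm
  expect_true(all(es@positions[, 1] >= 0 & es@positions[, 1] < lim[1]))
})

test_that("simulated event density matches the configured target within 10%", {
  for (case in list(c("star", 68.8), c("array", 3.8), c("lines", 19.9))) {
    dens <- as.numeric(case[2])
    es <- generatePattern(case[1], dens, seed = 7)
    tt <- simulateBlinking(es, nFrames = 1000, seed = 7)
    got <- nLocalizations(tt) / 1000
    expect_gt(got, 0.9 * dens)
    expect_lt(got, 1.1 * dens)
  }
})

test_that("blinking is seed-deterministic with the expected event count", {
  es <- generatePattern("lines", 19.9, seed = 3)
  a <- simulateBlinking(es, nFrames = 200, seed = 11)
  b <- simulateBlinking(es, nFrames = 200, seed = 11)
  expect_identical(locData(a), locData(b))

  empty <- new("EmitterSet", positions = matrix(numeric(), 0, 2),
               patternName = "array", fieldPx = c(180L, 180L), pixelNm = 100)
  expect_identical(nLocalizations(simulateBlinking(empty, nFrames = 10)), 0L)

  # closed-form stationary expectation vs simulation, 3 SD band
  ph <- Photophysics(pOn = 0.01, meanOnFrames = 2)
  n <- 1000L; T <- 2000L
  es2 <- new("EmitterSet",
             positions = cbind(runif(n, 0, 17999), runif(n, 0, 17999)),
             patternName = "array", fieldPx = c(180L, 180L), pixelNm = 100)
  tt <- simulateBlinking(es2, ph, nFrames = T, seed = 5)
  piOn <- ph@pOn / (ph@pOn + 1 / ph@meanOnFrames)
  expected <- n * piOn * T
  nBlinks <- expected / ph@meanOnFrames
  sdTot <- sqrt(nBlinks * (2 * ph@meanOnFrames^2 - ph@meanOnFrames))
  expect_lt(abs(nLocalizations(tt) - expected), 3 * sdTot)
})

test_that("noiseless rendering conserves photons over the baseline", {
  cam <- CameraModel(baseline = 200, poissonNoise = FALSE)
  empty <- LocalizationTable(data.frame(frame = integer(), x = numeric(),
                                        y = numeric(), intensity = numeric()),
                             provenance = "generative")
  fs <- renderFrames(empty, cam, 130, nFrames = 3, fieldPx = c(24L, 24L))
  expect_true(all(frameData(fs) == 200))

  one <- LocalizationTable(data.frame(frame = 1L, x = 1200, y = 1450,
                                      intensity = 5000),
                           provenance = "generative")
  fs1 <- renderFrames(one, cam, 130, nFrames = 1, fieldPx = c(24L, 24L))
  excess <- sum(frameData(fs1)) - 200 * 24 * 24
  expect_lt(abs(excess - 5000) / 5000, 0.001)

  expect_error(renderFrames(one, cam, 130, fieldPx = c(4L, 4L)), "wider")
})

test_that("Poisson camera noise averages to the configured baseline", {
  set.seed(21)
  empty <- LocalizationTable(data.frame(frame = integer(), x = numeric(),
                                        y = numeric(), intensity = numeric()),
                             provenance = "generative")
  fs <- renderFrames(empty, CameraModel(200, TRUE), 130, nFrames = 10000,
                     fieldPx = c(16L, 16L))
  pixMean <- apply(frameData(fs), c(1, 2), mean)
  expect_lt(abs(mean(pixMean) - 200), 0.05)
  expect_true(all(abs(pixMean - 200) < 5 * sqrt(200 / 10000)))
  expect_true(all(frameData(fs) >= 0))
  expect_true(all(frameData(fs) == round(frameData(fs))))
})

test_that("background stacks honour spatial and temporal specs", {
  spec <- BackgroundSpec("uniform", amplitude = 37, frozenTexture = FALSE)
  bg <- makeBackground(spec, nFrames = 4)
  expect_true(all(frameData(bg) == 37))

  expect_error(makeBackground(
    BackgroundSpec("uniform", amplitude = 10, temporal = "decaying",
                   keyframes = c(1, .5, .4, -.1, .2)), 5))
  expect_error(BackgroundSpec("uniform", temporal = "decaying",
                              keyframes = c(1, .5, .6, .4, .3)),
               "nonincreasing")

  # decaying profile: hits the last keyframe exactly, monotone nonincreasing,
  # with slowing decay at the keyframe scale
  kf <- c(1.00, 0.55, 0.35, 0.27, 0.25)
  specD <- BackgroundSpec("dim_gradient", amplitude = 50,
                          temporal = "decaying", keyframes = kf,
                          frozenTexture = FALSE)
  prof <- temporalProfile(specD, 500)
  expect_equal(prof[500], 0.25)
  expect_equal(prof[1], 1.00)
  expect_true(all(diff(prof) <= 1e-12))
  expect_true(all(diff(abs(diff(kf))) < 0))
  bgD <- makeBackground(specD, 200)
  series <- frameData(bgD)[10, 170, ]
  expect_true(all(diff(series) <= 1e-9))

  # bright gradient peak exceeds the brightest expected single-event pixel
  specB <- BackgroundSpec("bright_gradient")
  expect_gt(specB@amplitude, peakPixelExpectation())
})

test_that("frozen texture and combination are deterministic", {
  spec <- BackgroundSpec("multiple_puncta", amplitude = 300)
  a <- makeBackground(spec, 3, seed = 9)
  b <- makeBackground(spec, 3, seed = 9)
  expect_identical(frameData(a), frameData(b))
  # texture is frozen: every frame identical for a constant profile
  expect_identical(frameData(a)[, , 1], frameData(a)[, , 3])

  sig <- FrameStack(array(5, dim = c(8, 8, 3)))
  zero <- FrameStack(array(0, dim = c(8, 8, 3)))
  expect_identical(frameData(combineStacks(sig, zero)), frameData(sig))
  cst <- combineStacks(FrameStack(array(2, dim = c(8, 8, 3))),
                       FrameStack(array(3, dim = c(8, 8, 3))))
  expect_true(all(frameData(cst) == 5))
  expect_error(combineStacks(sig, FrameStack(array(0, dim = c(4, 4, 3)))),
               "shape")
})
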