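test_that("wavelet detection matches a direct convolution oracle", {
  flat <- matrix(80, 24, 24)
  expect_identical(nrow(waveletDetect(flat)$candidates), 0L)
  expect_error(waveletDetect(matrix(1, 3, 3)), "kernel")

  img <- spotFrame(1150, 950, photons = 3000, baseline = 10, fieldPx = 24)
  det <- waveletDetect(img)
  expect_identical(nrow(det$candidates), 1L)
  ow <- oracleWavelet(img)
  expect_equal(det$threshold, 2 * sqrt(mean((ow$W1 - mean(ow$W1))^2)),
               tolerance = 1e-10)
  pk <- which(ow$W2 == max(ow$W2), arr.ind = TRUE)
  expect_identical(as.integer(det$candidates[1, ]), as.integer(pk[1, ]))

  # two narrow spots three pixels apart resolve into two candidates
  img2 <- spotFrame(900, 1000, photons = 3000, sigmaNm = 60, baseline = 10,
                    fieldPx = 24) +
          spotFrame(1200, 1000, photons = 3000, sigmaNm = 60, baseline = 0,
                    fieldPx = 24)
  det2 <- waveletDetect(img2)
  expect_identical(nrow(det2$candidates), 2L)
})

test_that("integrated-Gaussian MLE recovers noiseless positions to <1 nm", {
  # spot at a pixel centre
  img <- spotFrame(1150, 950, photons = 2000, baseline = 5, fieldPx = 24)
  cand <- waveletDetect(img)$candidates
  row <- fitSpot(img, cand[1, ], frameIndex = 1L)
  expect_lt(abs(row$x - 1150), 1)
  expect_lt(abs(row$y - 950), 1)
  expect_lt(abs(row$sigma - 130), 5)
  expect_lt(abs(row$intensity - 2000) / 2000, 0.02)

  # known subpixel offset (+37, -12) nm
  img2 <- spotFrame(1187, 938, photons = 2000, baseline = 5, fieldPx = 24)
  row2 <- fitSpot(img2, waveletDetect(img2)$candidates[1, ])
  expect_lt(abs(row2$x - 1187), 1)
  expect_lt(abs(row2$y - 938), 1)

  # edge candidate without a full window is dropped
  expect_identical(nrow(fitSpot(img, c(2L, 2L))), 0L)
})

test_that("fit precision is within a factor 2 of the CRLB", {
  set.seed(99)
  n <- 150
  xs <- numeric(n)
  for (i in seq_len(n)) {
    img <- spotFrame(1150, 950, photons = 2000, baseline = 20, fieldPx = 24,
                     noise = TRUE)
    cand <- waveletDetect(img)$candidates
    expect_gte(nrow(cand), 1)
    xs[i] <- fitSpot(img, cand[1, ])$x
  }
  rmse <- sqrt(mean((xs - 1150)^2))
  sa2 <- 130^2 + 100^2 / 12
  crlb <- sqrt(sa2 / 2000 * (16 / 9 + 8 * pi * sa2 * 20 / (2000 * 100^2)))
  expect_lt(rmse, 2 * crlb)
  expect_gt(rmse, crlb / 2)
})

test_that("the quality filter is a pure strict predicate", {
  rows <- data.frame(frame = 1:4, x = 0, y = 0,
                     intensity = c(501, 500, 900, 900),
                     sigma = c(51, 100, 200, 120),
                     uncertainty = c(29, 10, 10, 30),
                     offset = 0)
  kept <- locData(filterTable(LocalizationTable(rows)))
  expect_identical(kept$frame, 1L)   # strict > and < on every bound

  set.seed(5)
  n <- 400
  tab <- data.frame(frame = seq_len(n), x = runif(n, 0, 100),
                    y = runif(n, 0, 100),
                    intensity = runif(n, 0, 1500),
                    sigma = runif(n, 10, 250),
                    uncertainty = runif(n, 0, 60), offset = 0)
  oracle <- tab[tab$intensity > 500 & tab$sigma > 50 & tab$sigma < 200 &
                  tab$uncertainty < 30, ]
  got <- locData(filterTable(LocalizationTable(tab)))
  expect_equal(got$frame, oracle$frame)
})

test_that("reblink merging follows the 40 nm / 20 frame rule", {
  mk <- function(df) LocalizationTable(cbind(df, sigma = 130,
                                             uncertainty = 10, offset = 2))
  one <- mk(data.frame(frame = 5L, x = 100, y = 100, intensity = 900))
  expect_equal(locData(mergeReblinks(one))[, 1:4], locData(one)[, 1:4])

  near <- mk(data.frame(frame = c(10L, 12L), x = c(100, 130), y = c(100, 100),
                        intensity = c(1000, 3000)))
  m <- locData(mergeReblinks(near))
  expect_identical(nrow(m), 1L)
  expect_equal(m$x, (100 * 1000 + 130 * 3000) / 4000)  # photon-weighted
  expect_equal(m$intensity, 4000)
  expect_identical(m$frame, 10L)

  far <- mk(data.frame(frame = c(10L, 12L), x = c(100, 150), y = c(100, 100),
                       intensity = c(1000, 1000)))
  expect_identical(nrow(locData(mergeReblinks(far))), 2L)
  gap <- mk(data.frame(frame = c(10L, 31L), x = c(100, 110), y = c(100, 100),
                       intensity = c(1000, 1000)))
  expect_identical(nrow(locData(mergeReblinks(gap))), 2L)

  # merging never increases rows; centroids stay inside the member hull
  set.seed(77)
  tab <- randomTable(500, lim = 2000, seed = 77, frames = 50L)
  d <- locData(tab); d$sigma <- 130; d$uncertainty <- 10; d$offset <- 1
  mg <- locData(mergeReblinks(LocalizationTable(d)))
  expect_lte(nrow(mg), nrow(d))
  expect_true(all(mg$x >= min(d$x) & mg$x <= max(d$x)))
  expect_equal(sum(mg$intensity), sum(d$intensity))
})

test_that("drift correction recovers an injected linear drift within 10 nm", {
  ds <- smallDataset("array", 3.8, nFrames = 600L, seed = 13)
  d <- locData(ds$truth)
  cfg <- PostprocessConfig()
  # drift-free control: recovered trajectory below the render resolution
  dc0 <- driftCorrect(ds$truth, cfg)
  expect_lt(max(abs(dc0$drift$dx)), 20)
  expect_lt(max(abs(dc0$drift$dy)), 20)

  drift <- 50 * (d$frame - 1) / 599
  d2 <- d
  d2$x <- d$x + drift
  d2$y <- d$y - 0.4 * drift
  dc <- driftCorrect(LocalizationTable(d2, "generative"), cfg)
  # recovered span between the first and last bin centres (flat at the ends)
  span <- (max(dc$drift$dx) - min(dc$drift$dx))
  injectedSpan <- 50 * (max(d$frame[d$frame <= 600]) - 1) / 599 * 2 / 3
  expect_lt(abs(span - injectedSpan), 10)
  corrected <- locData(dc$table)
  resid <- corrected$x - d$x
  expect_lt(diff(range(resid)), 25)

  expect_error(driftCorrect(LocalizationTable(
    data.frame(frame = c(1L, 1L), x = c(1, 2), y = c(1, 2),
               intensity = 1)), cfg), "fewer frames|empty")
})

test_that("average shifted histogram conserves mass and matches brute force", {
  tab <- randomTable(800, lim = 1990, seed = 3)
  cfg <- PostprocessConfig()
  img <- renderASH(tab, cfg, fieldPx = c(20L, 20L))
  expect_identical(dim(img@data), c(200L, 200L))
  expect_equal(sum(img@data), 800)           # exact mass conservation
  expect_equal(img@pixelNm, 10)

  # brute-force oracle: average of four shifted 2-D histograms
  d <- locData(tab)
  n <- 200
  acc <- matrix(0, n, n)
  for (sx in c(0, 0.5)) for (sy in c(0, 0.5)) {
    ix <- pmin(pmax(floor(d$x / 10 - sx), 0), n - 1)
    iy <- pmin(pmax(floor(d$y / 10 - sy), 0), n - 1)
    for (k in seq_len(nrow(d)))
      acc[iy[k] + 1, ix[k] + 1] <- acc[iy[k] + 1, ix[k] + 1] + 0.25
  }
  expect_equal(img@data, acc)

  one <- LocalizationTable(data.frame(frame = 1L, x = 55, y = 105,
                                      intensity = 1000))
  i1 <- renderASH(one, cfg, fieldPx = c(20L, 20L))
  expect_equal(sum(i1@data), 1)
  expect_error(renderASH(LocalizationTable(
    data.frame(frame = integer(), x = numeric(), y = numeric(),
               intensity = numeric())), cfg), "empty")
})

test_that("reconstruction is deterministic and finds few false positives", {
  ds <- smallDataset("array", 3.8, nFrames = 100L, seed = 17)
  r1 <- reconstruct(ds$gtStack, filter = FALSE, drift = FALSE,
                    cameraOffset = 200)
  r2 <- reconstruct(ds$gtStack, filter = FALSE, drift = FALSE,
                    cameraOffset = 200)
  expect_identical(locData(r1$table), locData(r2$table))
  expect_gt(nLocalizations(r1$table), 0)

  # event-free corrected background yields almost no detections
  bg <- makeBackground(BackgroundSpec("bright_gradient"), 100, seed = 2)
  base <- renderFrames(LocalizationTable(
    data.frame(frame = integer(), x = numeric(), y = numeric(),
               intensity = numeric()), provenance = "generative"),
    CameraModel(), 130, nFrames = 100)
  stack <- combineStacks(base, bg)
  corr <- correctStack(stack, CorrectionConfig(gate = 50))$corrected
  rFP <- reconstruct(corr, filter = FALSE, drift = FALSE, render = FALSE)
  expect_lte(nLocalizations(rFP$table), 0.01 * nLocalizations(r1$table) + 2)
})
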