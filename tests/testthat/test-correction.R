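test_that("constant stacks give their own value as background for all variants", {
  fs <- FrameStack(array(13, dim = c(5, 5, 40)))
  for (scope in c("single", "moving")) for (stat in c("median", "mean")) {
    bg <- estimateBackground(fs, CorrectionConfig(scope, stat, gate = 10))
    expect_equal(frameData(bg), frameData(fs), tolerance = 1e-12)
  }
})

test_that("median tolerates sparse spikes where the mean breaks down", {
  # pixel series: 398 frames at 10 except frames 100-101 at 1000, gate 200
  T <- 398L
  arr <- array(10, dim = c(2, 2, T))
  arr[1, 1, 100:101] <- 1000
  fs <- FrameStack(arr)
  bgMed <- estimateBackground(fs, CorrectionConfig("moving", "median", 200))
  expect_equal(frameData(bgMed)[1, 1, ], rep(10, T), tolerance = 1e-9)
  bgMean <- estimateBackground(fs, CorrectionConfig("moving", "mean", 200))
  # group-1 mean by direct arithmetic: (198*10 + 2*1000) / 200
  expect_equal(max(frameData(bgMean)[1, 1, ]), (198 * 10 + 2 * 1000) / 200,
               tolerance = 1e-9)
  expect_true(all(frameData(bgMean)[1, 1, 1:100] > 10))
  # an unaffected pixel stays at 10 under either statistic
  expect_equal(frameData(bgMean)[2, 2, ], rep(10, T), tolerance = 1e-9)
})

test_that("subtraction matches the elementwise oracle", {
  set.seed(4)
  a <- array(rpois(10 * 10 * 50, 100), dim = c(10, 10, 50))
  b <- array(rpois(10 * 10 * 50, 100), dim = c(10, 10, 50))
  sa <- FrameStack(a); sb <- FrameStack(b)
  expect_equal(frameData(subtractBackground(sa, sb)),
               array(pmax(a - b, 0), dim = dim(a)))
  expect_equal(subtractBackground(sa, sb, clampAtZero = FALSE),
               array(a - b, dim = dim(a)))
  expect_true(all(frameData(subtractBackground(sa, sa)) == 0))
  # clamp definition on a single pixel
  one <- function(v) FrameStack(array(v, dim = c(1, 1, 1)))
  expect_equal(as.vector(frameData(subtractBackground(one(150), one(200)))), 0)
  expect_equal(as.vector(subtractBackground(one(150), one(200), FALSE)), -50)
  expect_error(subtractBackground(sa, one(1)), "shape")
})

test_that("gate equal to the stack length reproduces single-scope output", {
  set.seed(8)
  fs <- FrameStack(array(rpois(6 * 6 * 80, 50), dim = c(6, 6, 80)))
  mv <- estimateBackground(fs, CorrectionConfig("moving", "median", 80))
  sg <- estimateBackground(fs, CorrectionConfig("single", "median", 200))
  expect_identical(frameData(mv), frameData(sg))
  expect_error(estimateBackground(fs, CorrectionConfig("moving", "median", 81)),
               "exceeds")
})

test_that("breakdown robustness: sub-50% contamination leaves the median exact", {
  # noiseless background 7 plus events in strictly fewer than half the frames
  # of every gate window -> moving-median background is exactly 7 everywhere
  T <- 60L
  arr <- array(7, dim = c(4, 4, T))
  for (g in 0:5) {
    hot <- g * 10 + seq_len(4)      # 4 of 10 frames contaminated per window
    arr[2, 3, hot] <- arr[2, 3, hot] + 500
    arr[1, 1, hot] <- arr[1, 1, hot] + 90
  }
  fs <- FrameStack(arr)
  bg <- estimateBackground(fs, CorrectionConfig("moving", "median", 10))
  expect_equal(frameData(bg), array(7, dim = dim(arr)), tolerance = 1e-12)
  corr <- correctStack(fs, CorrectionConfig("moving", "median", 10))
  expect_equal(max(frameData(corr$corrected)[2, 3, ]), 500)
})

test_that("correction preserves order and scales equivariantly", {
  set.seed(12)
  arr <- array(rpois(8 * 8 * 60, 80), dim = c(8, 8, 60))
  fs <- FrameStack(arr)
  cfg <- CorrectionConfig("moving", "median", 20)
  corr <- correctStack(fs, cfg)$corrected
  expect_true(all(frameData(corr) <= arr))
  for (stat in c("median", "mean")) {
    cfgS <- CorrectionConfig("moving", stat, 20)
    bg1 <- estimateBackground(fs, cfgS)
    bg2 <- estimateBackground(FrameStack(2.5 * arr), cfgS)
    expect_equal(frameData(bg2), 2.5 * frameData(bg1), tolerance = 1e-9)
  }
})

test_that("gate sweep validates gates and treats constant backgrounds alike", {
  ds <- smallDataset("array", 3.8, BackgroundSpec("uniform"), nFrames = 80L,
                     seed = 31)
  gtRec <- reconstruct(correctStack(ds$gtStack,
                                    CorrectionConfig(gate = 20))$corrected,
                       filter = FALSE, drift = FALSE,
                       provenance = "ground_truth")
  expect_error(gateSweep(ds$combined, gtRec$table, gates = c(20, 100)),
               "invalid gates")
  sw <- gateSweep(ds$combined, gtRec$table, gates = c(16, 40),
                  gtImage = gtRec$image, filter = FALSE, drift = FALSE)
  expect_identical(nrow(sw), 2L)
  # temporally constant background: both gates remove it equally well
  expect_lt(abs(sw$meanCbc[1] - sw$meanCbc[2]), 0.05)
  expect_true(all(sw$percentEvents > 50))
})
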