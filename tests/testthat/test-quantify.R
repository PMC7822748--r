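# synthetic annulus field: rings rendered as intensity on |r - R| <= 1 px
annulusImage <- function(centersPx, diametersNm, n = 400, pixelNm = 10,
                         amp = 30, noiseSd = 0) {
  img <- matrix(0, n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  row <- matrix(seq_len(n), n, n)
  for (i in seq_len(nrow(centersPx))) {
    r <- diametersNm[i] / 2 / pixelNm
    d <- sqrt((col - centersPx[i, 1])^2 + (row - centersPx[i, 2])^2)
    img[abs(d - r) <= 1] <- img[abs(d - r) <= 1] + amp
  }
  if (noiseSd > 0) img <- img + matrix(abs(rnorm(n * n, 0, noiseSd)), n, n)
  img
}

test_that("ring detection recovers synthetic annuli with correct diameters", {
  expect_identical(nrow(detectRings(matrix(0, 200, 200), pixelNm = 10)), 0L)

  set.seed(44)
  nr <- 10
  cx <- rep(seq(60, 360, length.out = 5), 2)
  cy <- rep(c(100, 280), each = 5)
  dia <- seq(60, 200, length.out = nr)
  img <- annulusImage(cbind(cx, cy), dia, noiseSd = 1.5)
  rings <- detectRings(img, pixelNm = 10)
  expect_identical(nrow(rings), as.integer(nr))
  # match detections to truth and check diameters within 2 render pixels
  for (i in seq_len(nr)) {
    dd <- sqrt((rings$x_nm - cx[i] * 10)^2 + (rings$y_nm - cy[i] * 10)^2)
    j <- which.min(dd)
    expect_lt(dd[j], dia[i] / 2)
    expect_lte(abs(rings$diameter_nm[j] - dia[i]), 20)
  }
})

test_that("ring density is count over area", {
  expect_equal(ringDensity(data.frame(), 10), 0)
  expect_equal(ringDensity(data.frame(x = seq_len(50)), 250), 0.2)
  expect_error(ringDensity(data.frame(), 0), "positive")
})

test_that("manual click-lists round trip into the ring workflow", {
  path <- file.path(tempdir(), "rings.csv")
  write.csv(data.frame(x_nm = c(100, 900), y_nm = c(200, 250),
                       diameter_nm = c(80, 120)), path, row.names = FALSE)
  rings <- readRings(path)
  expect_identical(nrow(rings), 2L)
  expect_true(all(is.na(rings$score)))
  expect_equal(ringDensity(rings, 10), 0.2)
  write.csv(data.frame(x_nm = 1, y_nm = 2), path, row.names = FALSE)
  expect_error(readRings(path), "diameter_nm")
})

test_that("diameter statistics report mean, SD and fitted mode", {
  same <- rep(85, 20)
  s <- diameterStats(same)
  expect_equal(s$mean, 85)
  expect_equal(s$sd, 0)
  expect_lt(abs(s$mode - 85), 10)

  set.seed(9)
  d <- rnorm(1000, 80, 19)
  s2 <- diameterStats(d)
  expect_lt(abs(s2$mode - 80), 2.5)
  expect_lt(abs(s2$modeSd - 19), 4)

  # right-skewed sample: mean exceeds the Gaussian mode
  set.seed(10)
  dsk <- c(rnorm(700, 80, 15), runif(300, 100, 250))
  s3 <- diameterStats(dsk)
  expect_gt(s3$mean, s3$mode)
  expect_error(diameterStats(c(80, 90)), "at least 3")
})

test_that("marker coverage follows the 75%-of-maximum threshold rule", {
  mask <- matrix(FALSE, 40, 40); mask[6:35, 6:35] <- TRUE
  marker <- matrix(0, 40, 40); marker[mask] <- 100
  cov <- markerCoverage(marker, mask, pixelNm = 10)
  expect_equal(cov$coverage, 100)
  expect_equal(cov$cellAreaUm2, sum(mask) * 1e-4)

  # half the cell above threshold -> 50%
  half <- matrix(0, 40, 40)
  half[6:35, 6:20] <- 100   # 15 of 30 columns
  half[6:35, 21:35] <- 10   # below 75 = 0.75 * 100
  cov2 <- markerCoverage(half, mask, pixelNm = 10)
  expect_equal(cov2$coverage, 50)
  expect_lte(cov2$markerAreaUm2, cov2$cellAreaUm2)

  # adding above-threshold pixels never decreases coverage
  more <- half; more[6:35, 21:25] <- 95
  expect_gte(markerCoverage(more, mask)$coverage,
             markerCoverage(half, mask)$coverage)

  expect_error(markerCoverage(half, matrix(FALSE, 40, 40)), "empty")
  expect_error(markerCoverage(half, matrix(TRUE, 10, 10)), "grid")

  # iterative-intermeans alternative stays within [0, 100]
  cov3 <- markerCoverage(half, mask, autoThreshold = TRUE)
  expect_true(cov3$coverage >= 0 && cov3$coverage <= 100)
})
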