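#' Wavelet pre-detection of candidate spots
#'
#' B-spline a-trous wavelet decomposition (order 3, scale 2) of one frame;
#' candidates are 8-connected local maxima of the second wavelet plane
#' exceeding \code{thresholdMult} standard deviations of the first wavelet
#' plane (recomputed per frame, which adapts the threshold to decaying
#' backgrounds). Plateau ties go to the lowest (row, col).
#'
#' @param frame numeric matrix (one movie frame).
#' @param config a \linkS4class{DetectionConfig}.
#' @return List with \code{candidates} (m x 2 matrix of 1-based row, col) and
#'   \code{threshold}.
#' @export
waveletDetect <- function(frame, config = DetectionConfig()) {
  res <- cpp_wavelet_detect(frame, config@thresholdMult, 1L)
  cand <- res$candidates
  if (nrow(cand)) cand <- cand + 1L
  colnames(cand) <- c("row", "col")
  list(candidates = cand, threshold = res$threshold, sd1 = res$sd1)
}

.mortensen <- function(sigmaNm, photons, bgPerPixel, pixelNm) {
  sa2 <- sigmaNm^2 + pixelNm^2 / 12
  v <- sa2 / photons *
    (16 / 9 + 8 * pi * sa2 * pmax(bgPerPixel, 0) / (photons * pixelNm^2))
  sqrt(pmax(v, 1e-12))
}

.fitCandidates <- function(frame, candidates, config, pixelNm, frameIndex) {
  empty <- matrix(numeric(), 0, 7,
                  dimnames = list(NULL, c("frame", "x", "y", "intensity",
                                          "sigma", "uncertainty", "offset")))
  if (nrow(candidates) == 0) return(empty)
  m <- cpp_fit_spots(frame, candidates - 1L, config@fitRadiusPx,
                     1.3, 50L, 1e-6)
  if (nrow(m) == 0) return(empty)
  ok <- m[, 6] > 0   # converged fits only; the rest are dropped
  m <- m[ok, , drop = FALSE]
  sigmaNm <- m[, 5] * pixelNm
  out <- cbind(frame = rep(frameIndex, nrow(m)),
               x = m[, 1] * pixelNm, y = m[, 2] * pixelNm,
               intensity = m[, 3], sigma = sigmaNm,
               uncertainty = .mortensen(sigmaNm, m[, 3], m[, 4], pixelNm),
               offset = m[, 4])
  out
}

.rowsToTable <- function(m) {
  data.frame(frame = as.integer(m[, "frame"]), x = m[, "x"], y = m[, "y"],
             intensity = m[, "intensity"], sigma = m[, "sigma"],
             uncertainty = m[, "uncertainty"], offset = m[, "offset"])
}

#' Fit one candidate spot by integrated-Gaussian maximum likelihood
#'
#' Maximises the Poisson likelihood of a symmetric integrated Gaussian plus
#' constant offset over the (2 r + 1)^2 window around the candidate
#' (Fisher-scoring iterations with step damping; initialised at the window
#' centroid, sigma 1.3 px, the window minimum for the offset). Candidates
#' without a full window are dropped. The lateral uncertainty is the
#' Thompson/Mortensen precision for the fitted photon count, sigma and local
#' background.
#'
#' @param frame numeric matrix.
#' @param candidate integer (row, col), 1-based.
#' @param config a \linkS4class{DetectionConfig}.
#' @param pixelNm pixel size in nm.
#' @param frameIndex frame number recorded in the output row.
#' @return One-row data.frame (or zero rows if the fit was dropped) with
#'   frame, x, y (nm), intensity (photons), sigma (nm), uncertainty (nm),
#'   offset (counts).
#' @export
fitSpot <- function(frame, candidate, config = DetectionConfig(),
                    pixelNm = 100, frameIndex = 1L) {
  .rowsToTable(.fitCandidates(frame, matrix(as.integer(candidate), 1, 2),
                              config, pixelNm, frameIndex))
}

#' Quality-filter a reconstruction table
#'
#' Retains rows satisfying all four strict inequalities
#' intensity > 500, 50 < sigma < 200, uncertainty < 30 (row order preserved).
#'
#' @param table a \linkS4class{LocalizationTable} with fitted columns.
#' @param intensityMin,sigmaMin,sigmaMax,uncertaintyMax filter bounds.
#' @return The filtered \linkS4class{LocalizationTable}.
#' @export
filterTable <- function(table, intensityMin = 500, sigmaMin = 50,
                        sigmaMax = 200, uncertaintyMax = 30) {
  d <- locData(table)
  keep <- d$intensity > intensityMin & d$sigma > sigmaMin &
    d$sigma < sigmaMax & d$uncertainty < uncertaintyMax
  LocalizationTable(d[keep, , drop = FALSE], provenance = provenance(table))
}

#' Merge reblinking events
#'
#' Greedy chaining in frame order: an event joins an open track when it lies
#' within \code{mergeRadiusNm} of the track's photon-weighted running centroid
#' and within \code{mergeFrames} frames of its last member. A merged row is
#' the photon-weighted centroid with summed intensity and the first frame.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param config a \linkS4class{PostprocessConfig}.
#' @return The merged \linkS4class{LocalizationTable}.
#' @export
mergeReblinks <- function(table, config = PostprocessConfig()) {
  d <- locData(table)
  if (nrow(d) < 2) return(table)
  d <- d[order(d$frame), , drop = FALSE]
  sg <- if ("sigma" %in% names(d)) d$sigma else rep(1, nrow(d))
  un <- if ("uncertainty" %in% names(d)) d$uncertainty else rep(1, nrow(d))
  of <- if ("offset" %in% names(d)) d$offset else rep(0, nrow(d))
  m <- cpp_merge_reblinks(as.integer(d$frame), d$x, d$y, d$intensity,
                          sg, un, of, config@mergeRadiusNm,
                          as.integer(config@mergeFrames))
  out <- data.frame(frame = as.integer(m[, 1]), x = m[, 2], y = m[, 3],
                    intensity = m[, 4], sigma = m[, 5],
                    uncertainty = m[, 6], offset = m[, 7])
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  LocalizationTable(out, provenance = provenance(table))
}

.hist2d <- function(x, y, n, px, sx = 0, sy = 0) {
  ix <- pmin(pmax(floor(x / px - sx), 0), n - 1)
  iy <- pmin(pmax(floor(y / px - sy), 0), n - 1)
  matrix(tabulate(iy + n * ix + 1, nbins = n * n), n, n)
}

.ccShift <- function(a, b) {
  # displacement of b relative to a (rows, cols) via circular
  # cross-correlation with parabolic subpixel refinement
  n <- nrow(a)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  val <- function(dr, dc)
    cc[(pk[1] - 1 + dr) %% n + 1, (pk[2] - 1 + dc) %% n + 1]
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else 0.5 * (cm - cp) / den
  }
  s1 <- pk[1] - 1; if (s1 > n / 2) s1 <- s1 - n
  s2 <- pk[2] - 1; if (s2 > n / 2) s2 <- s2 - n
  s1 <- s1 + para(val(-1, 0), val(0, 0), val(1, 0))
  s2 <- s2 + para(val(0, -1), val(0, 0), val(0, 1))
  -c(s1, s2)
}

#' Cross-correlation drift correction
#'
#' Splits the table into temporal bins, renders each bin as a 2-D histogram at
#' \code{driftMag}-fold magnification, registers later bins to the first by
#' the cross-correlation peak with parabolic subpixel refinement, interpolates
#' the bin shifts linearly between bin-centre frames (held flat at the stack
#' ends), and shifts every localization accordingly.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param config a \linkS4class{PostprocessConfig}.
#' @param fieldPx,pixelNm source-stack geometry.
#' @return List with the corrected \code{table} and a \code{drift} data.frame
#'   (frame, dx, dy in nm).
#' @export
driftCorrect <- function(table, config = PostprocessConfig(),
                         fieldPx = c(180L, 180L), pixelNm = 100) {
  d <- locData(table)
  nb <- config@driftBins
  if (nrow(d) == 0 || diff(range(d$frame)) + 1 < nb)
    stop("table spans fewer frames than drift bins")
  edges <- seq(min(d$frame) - 0.5, max(d$frame) + 0.5, length.out = nb + 1)
  bin <- cut(d$frame, edges, labels = FALSE)
  if (any(tabulate(bin, nb) == 0))
    stop("empty drift bin; use fewer bins")
  px <- pixelNm / config@driftMag
  n <- max(fieldPx) * config@driftMag
  # bin histograms are sparse at the render pitch; a light B-spline blur
  # (~1.3 render px) makes the correlation peak robust to fit jitter
  b3 <- c(1, 4, 6, 4, 1) / 16
  kb <- outer(b3, b3)
  imgs <- lapply(seq_len(nb), function(b) {
    h <- .hist2d(d$x[bin == b], d$y[bin == b], n, px)
    .convSame(.convSame(h, kb), kb)
  })
  centers <- vapply(seq_len(nb), function(b) mean(d$frame[bin == b]),
                    numeric(1))
  shifts <- rbind(c(0, 0), t(vapply(2:nb, function(b)
    .ccShift(imgs[[1]], imgs[[b]]), numeric(2))))
  # rows of .hist2d are y: shift[ ,1] is dy, shift[ ,2] is dx (in render px)
  fr <- seq(min(d$frame), max(d$frame))
  tc <- pmin(pmax(fr, centers[1]), centers[nb])
  dy <- stats::approx(centers, shifts[, 1], xout = tc)$y * px
  dx <- stats::approx(centers, shifts[, 2], xout = tc)$y * px
  idx <- d$frame - min(d$frame) + 1L
  d$x <- d$x - dx[idx]
  d$y <- d$y - dy[idx]
  list(table = LocalizationTable(d, provenance = provenance(table)),
       drift = data.frame(frame = fr, dx = dx, dy = dy))
}

#' Average shifted histogram rendering
#'
#' Renders the table at \code{renderMag}-fold magnification (10 nm pixels at
#' defaults) as the average of a 2 x 2 lattice of half-pixel-shifted 2-D
#' histograms. Total mass equals the number of rows exactly.
#'
#' @param table a nonempty \linkS4class{LocalizationTable}.
#' @param config a \linkS4class{PostprocessConfig}.
#' @param fieldPx,pixelNm source-stack geometry.
#' @return A \linkS4class{RenderedImage} of size fieldPx * renderMag.
#' @export
renderASH <- function(table, config = PostprocessConfig(),
                      fieldPx = c(180L, 180L), pixelNm = 100) {
  d <- locData(table)
  if (nrow(d) == 0) stop("cannot render an empty table")
  px <- pixelNm / config@renderMag
  n <- max(fieldPx) * config@renderMag
  acc <- matrix(0, n, n)
  for (sx in c(0, 0.5)) for (sy in c(0, 0.5))
    acc <- acc + .hist2d(d$x, d$y, n, px, sx, sy)
  RenderedImage(acc / 4, pixelNm = px)
}

#' Reconstruct a super-resolution table and image from a movie
#'
#' The full pipeline: per-frame wavelet detection, integrated-Gaussian MLE
#' fitting, optional quality filtering, reblink merging, cross-correlation
#' drift correction and average-shifted-histogram rendering.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param detectionConfig a \linkS4class{DetectionConfig}.
#' @param postprocessConfig a \linkS4class{PostprocessConfig}.
#' @param filter apply the intensity/sigma/uncertainty filter (off for
#'   simulated validation data, matching how such data are processed).
#' @param drift apply drift correction.
#' @param render build the rendered image.
#' @param cameraOffset camera baseline counts subtracted (clamped at zero)
#'   from every frame before analysis, so fitting operates on photon-scale
#'   data. Use the camera baseline for raw stacks and 0 for
#'   background-corrected stacks, whose baseline was already removed by the
#'   correction.
#' @param provenance provenance tag for the output table.
#' @return List with \code{table} (\linkS4class{LocalizationTable}),
#'   \code{image} (\linkS4class{RenderedImage} or NULL), \code{drift}, and a
#'   \code{log} of per-stage counts.
#' @export
reconstruct <- function(stack, detectionConfig = DetectionConfig(),
                        postprocessConfig = PostprocessConfig(),
                        filter = TRUE, drift = TRUE, render = TRUE,
                        cameraOffset = 0, provenance = "reconstruction") {
  d <- stack@data
  T <- dim(d)[3L]
  fieldPx <- c(dim(d)[2L], dim(d)[1L])
  rows <- vector("list", T)
  nCand <- 0L
  for (t in seq_len(T)) {
    fr <- d[, , t]
    if (cameraOffset > 0) fr <- pmax(fr - cameraOffset, 0)
    det <- waveletDetect(fr, detectionConfig)
    nCand <- nCand + nrow(det$candidates)
    rows[[t]] <- .fitCandidates(fr, det$candidates, detectionConfig,
                                stack@pixelNm, t)
  }
  tab <- .rowsToTable(do.call(rbind, rows))
  nFit <- nrow(tab)
  loc <- LocalizationTable(tab, provenance = provenance)
  if (filter) loc <- filterTable(loc)
  nKept <- nLocalizations(loc)
  loc <- mergeReblinks(loc, postprocessConfig)
  nMerged <- nLocalizations(loc)
  driftTraj <- NULL
  if (drift && nMerged > 0) {
    dc <- driftCorrect(loc, postprocessConfig, fieldPx, stack@pixelNm)
    loc <- dc$table
    driftTraj <- dc$drift
  }
  img <- if (render && nLocalizations(loc) > 0)
    renderASH(loc, postprocessConfig, fieldPx, stack@pixelNm) else NULL
  list(table = loc, image = img, drift = driftTraj,
       log = list(candidates = nCand, fitted = nFit, kept = nKept,
                  merged = nMerged))
}
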