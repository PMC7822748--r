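.convSame <- function(img, kern) {
  # 'same'-size linear convolution with zero padding, via FFT
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kern); kw <- ncol(kern)
  ph <- H + kh - 1; pw <- W + kw - 1
  a <- matrix(0, ph, pw); a[1:H, 1:W] <- img
  b <- matrix(0, ph, pw); b[1:kh, 1:kw] <- kern
  full <- Re(fft(fft(a) * fft(b), inverse = TRUE)) / (ph * pw)
  r0 <- (kh - 1) %/% 2; c0 <- (kw - 1) %/% 2
  full[(r0 + 1):(r0 + H), (c0 + 1):(c0 + W)]
}

.ringKernels <- function(diameterNm, pixelNm) {
  r <- diameterNm / 2 / pixelNm
  k <- 2 * ceiling(r + 2) + 1
  c0 <- (k + 1) / 2
  dist <- sqrt(outer((1:k - c0)^2, (1:k - c0)^2, "+"))
  ring <- abs(dist - r) <= 1
  disk <- dist <= max(r - 2, 0.8)
  list(ring = ring / sum(ring), disk = disk / sum(disk))
}

#' Detect nanoscale ring structures in a rendered image
#'
#' Annulus-template matching over a diameter range: for each template the
#' contrast (mean intensity on the ring minus mean intensity inside the disk)
#' is computed at every position; ring candidates are local maxima of the
#' best-template contrast above a threshold, greedily pruned so that no
#' accepted centre lies within one detected diameter of a stronger one
#' (physical rings cannot overlap that closely). The reported diameter
#' (peak-to-peak) is the template with maximal contrast at the centre.
#'
#' @param img a \linkS4class{RenderedImage} or matrix.
#' @param pixelNm pixel size of the image in nm (taken from a RenderedImage).
#' @param dRangeNm diameter search range, default 50-250 nm.
#' @param dStepNm template spacing (default two render pixels).
#' @param minScore contrast threshold; NULL picks 5 SD of the contrast map.
#' @return data.frame with columns x_nm, y_nm, diameter_nm, score (possibly
#'   zero rows).
#' @export
detectRings <- function(img, pixelNm = 10, dRangeNm = c(50, 250),
                        dStepNm = NULL, minScore = NULL) {
  if (is(img, "RenderedImage")) { pixelNm <- img@pixelNm; img <- img@data }
  if (is.null(dStepNm)) dStepNm <- 2 * pixelNm
  diams <- seq(dRangeNm[1], dRangeNm[2], by = dStepNm)
  H <- nrow(img); W <- ncol(img)
  best <- matrix(-Inf, H, W); bestD <- matrix(diams[1], H, W)
  for (d in diams) {
    kk <- .ringKernels(d, pixelNm)
    sc <- .convSame(img, kk$ring) - .convSame(img, kk$disk)
    upd <- sc > best
    best[upd] <- sc[upd]
    bestD[upd] <- d
  }
  if (is.null(minScore)) minScore <- 5 * stats::sd(best) + 1e-9
  # local maxima of the contrast map above threshold
  mrg <- ceiling(dRangeNm[1] / 2 / pixelNm)
  cand <- which(best > minScore, arr.ind = TRUE)
  cand <- cand[cand[, 1] > mrg & cand[, 1] <= H - mrg &
               cand[, 2] > mrg & cand[, 2] <= W - mrg, , drop = FALSE]
  if (nrow(cand)) {
    ismax <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1]; c <- cand[i, 2]
      nb <- best[(r - 1):(r + 1), (c - 1):(c + 1)]
      best[r, c] >= max(nb)
    }, logical(1))
    cand <- cand[ismax, , drop = FALSE]
  }
  out <- data.frame(x_nm = numeric(), y_nm = numeric(),
                    diameter_nm = numeric(), score = numeric())
  if (nrow(cand) == 0) return(out)
  sc <- best[cand]
  ord <- order(sc, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; sc <- sc[ord]
  keptR <- numeric(0); keptC <- numeric(0); keptI <- integer(0)
  keptD <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    dCand <- bestD[cand[i, 1], cand[i, 2]]
    if (length(keptR)) {
      dd <- sqrt((keptR - cand[i, 1])^2 + (keptC - cand[i, 2])^2)
      if (any(dd < pmax(keptD, dCand) / pixelNm)) next
      # arc ghosts: much weaker maxima in the close neighbourhood of an
      # accepted ring (within 1.5 diameters) are template side lobes
      ghost <- dd < 1.5 * pmax(keptD, dCand) / pixelNm &
        sc[i] < 0.5 * sc[keptI]
      if (any(ghost)) next
    }
    keptR <- c(keptR, cand[i, 1]); keptC <- c(keptC, cand[i, 2])
    keptD <- c(keptD, dCand)
    keptI <- c(keptI, i)
  }
  data.frame(x_nm = (keptC - 0.5) * pixelNm, y_nm = (keptR - 0.5) * pixelNm,
             diameter_nm = bestD[cbind(keptR, keptC)], score = sc[keptI])
}

#' Read a ring annotation list from CSV
#'
#' Ingests either the output of \code{\link{detectRings}} or a manual
#' click-list with columns \code{x_nm, y_nm, diameter_nm} (a \code{score}
#' column is optional and filled with NA when absent), so manually counted
#' rings can flow through \code{\link{ringDensity}} and
#' \code{\link{diameterStats}} unchanged.
#'
#' @param path .csv path.
#' @return data.frame with columns x_nm, y_nm, diameter_nm, score.
#' @export
readRings <- function(path) {
  d <- read.csv(path)
  need <- c("x_nm", "y_nm", "diameter_nm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (is.null(d$score)) d$score <- NA_real_
  if (any(d$diameter_nm <= 0)) stop("diameters must be positive")
  d[, c("x_nm", "y_nm", "diameter_nm", "score")]
}

#' Ring density per square micrometre
#'
#' @param rings data.frame from \code{\link{detectRings}} (or any object with
#'   one row per ring).
#' @param areaUm2 area surveyed, in square micrometres.
#' @return Rings per square micrometre.
#' @export
ringDensity <- function(rings, areaUm2) {
  if (areaUm2 <= 0) stop("area must be positive")
  nrow(rings) / areaUm2
}

#' Summary statistics of ring diameters
#'
#' Sample mean and SD, plus a least-squares Gaussian fit to the binned
#' diameter histogram whose fitted centre estimates the mode (diameter
#' distributions are right-skewed, so mode < mean is expected).
#'
#' @param diameters numeric vector of diameters (nm); at least 3 for fitting.
#' @param binWidthNm histogram bin width (10 nm).
#' @return List: mean, sd, mode (fitted centre, NA on fit failure), modeSd
#'   (fitted width).
#' @export
diameterStats <- function(diameters, binWidthNm = 10) {
  if (length(diameters) < 3) stop("need at least 3 diameters")
  m <- mean(diameters); s <- sd(diameters)
  breaks <- seq(floor(min(diameters) / binWidthNm) * binWidthNm,
                max(diameters) + binWidthNm, by = binWidthNm)
  h <- graphics::hist(diameters, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  mode <- NA_real_; modeSd <- NA_real_
  fit <- try({
    obj <- function(p) sum((y - p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)))^2)
    p0 <- c(max(y), x[which.max(y)], max(s, binWidthNm))
    optim(p0, obj)
  }, silent = TRUE)
  if (!inherits(fit, "try-error") && fit$convergence == 0 &&
      fit$par[2] > min(x) - binWidthNm && fit$par[2] < max(x) + binWidthNm) {
    mode <- fit$par[2]; modeSd <- abs(fit$par[3])
  } else {
    warning("Gaussian fit failed; mode not reported")
  }
  list(mean = m, sd = s, mode = mode, modeSd = modeSd)
}

.isodata <- function(v) {
  # iterative intermeans threshold (ImageJ default method)
  t0 <- mean(v)
  for (i in 1:100) {
    lo <- v[v <= t0]; hi <- v[v > t0]
    if (!length(lo) || !length(hi)) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < 1e-9) break
    t0 <- t1
  }
  t0
}

#' Membrane-marker area coverage
#'
#' Marker pixels are those above \code{thresholdFrac} of the image maximum
#' (the fixed-fraction reading of the thresholding rule; set
#' \code{autoThreshold} for an iterative-intermeans threshold instead),
#' intersected with the cell mask. Coverage is the marker area as a
#' percentage of the mask area.
#'
#' @param markerImg marker \linkS4class{RenderedImage} or matrix.
#' @param maskImg cell mask: logical matrix, or numeric (positive = cell). If
#'   NULL, an Otsu mask of the marker image is used (requires EBImage).
#' @param thresholdFrac fraction of the image maximum (0.75).
#' @param autoThreshold use the iterative intermeans threshold instead.
#' @param pixelNm pixel size in nm for areas in square micrometres.
#' @return List: cellAreaUm2, markerAreaUm2, coverage (percent).
#' @export
markerCoverage <- function(markerImg, maskImg = NULL, thresholdFrac = 0.75,
                           autoThreshold = FALSE, pixelNm = 10) {
  if (is(markerImg, "RenderedImage")) {
    pixelNm <- markerImg@pixelNm; markerImg <- markerImg@data
  }
  if (is.null(maskImg)) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("supply a mask or install EBImage for automatic masking")
    rng <- range(markerImg)
    sc <- (markerImg - rng[1]) / max(rng[2] - rng[1], 1e-12)
    mask <- sc > EBImage::otsu(EBImage::Image(sc))
  } else {
    if (is(maskImg, "RenderedImage")) maskImg <- maskImg@data
    mask <- if (is.logical(maskImg)) maskImg else maskImg > 0
  }
  if (!identical(dim(mask), dim(markerImg))) stop("mask grid differs")
  if (!any(mask)) stop("empty cell mask")
  thr <- if (autoThreshold) .isodata(as.vector(markerImg)) else
    thresholdFrac * max(markerImg)
  hits <- (markerImg > thr) & mask
  pxUm2 <- (pixelNm / 1000)^2
  list(cellAreaUm2 = sum(mask) * pxUm2, markerAreaUm2 = sum(hits) * pxUm2,
       coverage = 100 * sum(hits) / sum(mask))
}
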