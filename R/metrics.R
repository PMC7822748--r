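#' Percent of ground-truth events detected
#'
#' 100 * |test| / |ground truth|; may exceed 100 when a contaminated data set
#' over-detects.
#'
#' @param testTable,gtTable \linkS4class{LocalizationTable}s.
#' @return Percentage (numeric scalar).
#' @export
percentEvents <- function(testTable, gtTable) {
  ng <- nLocalizations(gtTable)
  if (ng == 0) stop("ground-truth table is empty")
  100 * nLocalizations(testTable) / ng
}

#' Coordinate-based colocalization
#'
#' For every ground-truth localization, the cumulative neighbour counts of the
#' ground-truth and test point sets over concentric radii up to
#' \code{radiusNm} are area-normalised and rank-correlated (Spearman); the
#' correlation is damped by exp(-d/radiusNm) with d the distance to the
#' nearest test event. Scores range from -1 (segregated) through 0 (random)
#' to 1 (colocalized); events with no neighbours in both channels score 0.
#'
#' @param gtTable,testTable \linkS4class{LocalizationTable}s.
#' @param radiusNm search radius (500 nm).
#' @param nBins number of concentric annuli (10).
#' @return List with per-event \code{values}, per-event nearest-neighbour
#'   \code{nnd} (nm), and the \code{mean} CBC.
#' @export
cbcScore <- function(gtTable, testTable, radiusNm = 500, nBins = 10L) {
  g <- locData(gtTable); s <- locData(testTable)
  if (nrow(g) == 0 || nrow(s) == 0) stop("both tables must be nonempty")
  m <- cpp_cbc(g$x, g$y, s$x, s$y, radiusNm, as.integer(nBins))
  list(values = m[, 1], nnd = m[, 2], mean = mean(m[, 1]))
}

#' Nearest neighbour distances, ground truth to test
#'
#' @param gtTable,testTable \linkS4class{LocalizationTable}s; the test table
#'   must be nonempty.
#' @return Numeric vector of distances (nm), one per ground-truth event.
#' @export
nndDistances <- function(gtTable, testTable) {
  g <- locData(gtTable); s <- locData(testTable)
  if (nrow(s) == 0) stop("test table is empty")
  cpp_nnd(g$x, g$y, s$x, s$y)
}

#' Image co-occurrence and correlation
#'
#' Mander's overlap coefficient sum(a b)/sqrt(sum(a^2) sum(b^2)) and the
#' pixel-wise Pearson correlation of two rendered images on identical grids.
#' Pearson is undefined (NA, with a warning) for a zero-variance image.
#'
#' @param imgA,imgB \linkS4class{RenderedImage}s or matrices of equal size.
#' @return Named list: \code{manders}, \code{pearson}.
#' @export
imageColoc <- function(imgA, imgB) {
  a <- if (is(imgA, "RenderedImage")) imgA@data else imgA
  b <- if (is(imgB, "RenderedImage")) imgB@data else imgB
  if (!identical(dim(a), dim(b))) stop("image grids differ")
  manders <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
  pearson <- if (va == 0 || vb == 0) {
    warning("zero-variance image: Pearson undefined")
    NA_real_
  } else cor(as.vector(a), as.vector(b))
  list(manders = manders, pearson = pearson)
}

#' Evaluate a reconstruction against its ground truth
#'
#' Computes the five comparison statistics (all referenced ground truth to
#' test): percent events, CBC (mean and 0.1-wide histogram over [-1, 1]),
#' nearest neighbour distance (mean and 0.1 nm binned histogram with an
#' overflow bin), and — when rendered images are supplied — Mander's overlap
#' and Pearson correlation.
#'
#' @param gtTable,testTable \linkS4class{LocalizationTable}s.
#' @param gtImage,testImage optional \linkS4class{RenderedImage}s.
#' @param radiusNm,nBins CBC parameters.
#' @return A \linkS4class{MetricReport}.
#' @export
evaluateReconstruction <- function(gtTable, testTable, gtImage = NULL,
                                   testImage = NULL, radiusNm = 500,
                                   nBins = 10L) {
  pe <- percentEvents(testTable, gtTable)
  cbc <- cbcScore(gtTable, testTable, radiusNm, nBins)
  cbcBreaks <- seq(-1, 1, by = 0.1)
  ch <- table(cut(pmin(pmax(cbc$values, -1), 1), cbcBreaks,
                  include.lowest = TRUE))
  cbcHist <- as.numeric(ch)
  names(cbcHist) <- names(ch)
  nnd <- cbc$nnd
  nndBreaks <- c(seq(0, 10, by = 0.1), Inf)
  nh <- table(cut(nnd, nndBreaks, include.lowest = TRUE))
  nndHist <- as.numeric(nh)
  names(nndHist) <- names(nh)
  co <- if (!is.null(gtImage) && !is.null(testImage))
    imageColoc(gtImage, testImage) else list(manders = NA_real_,
                                             pearson = NA_real_)
  new("MetricReport", percentEvents = pe, meanCbc = cbc$mean,
      cbcHist = cbcHist, meanNnd = mean(nnd), nndHist = nndHist,
      manders = co$manders, pearson = co$pearson)
}
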