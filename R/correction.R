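#' Estimate the background of a movie by grouped temporal projection
#'
#' Per pixel, the median (or mean) over consecutive non-overlapping
#' \code{gate}-frame blocks is computed; the resulting group images are then
#' interpolated back to one image per frame with a natural cubic through the
#' group-centre frame indices, held constant beyond the first and last centre.
#' Single scope is the special case gate = T (one projection broadcast to all
#' frames). The final partial group, if any, uses the frames it has.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param config a \linkS4class{CorrectionConfig}.
#' @return A \linkS4class{FrameStack} of per-frame background estimates.
#' @examples
#' fs <- FrameStack(array(7, dim = c(4, 4, 10)))
#' bg <- estimateBackground(fs, CorrectionConfig("moving", "median", gate = 5))
#' all(frameData(bg) == 7)
#' @export
estimateBackground <- function(stack, config) {
  validObject(config)
  d <- stack@data
  T <- dim(d)[3L]; H <- dim(d)[1L]; W <- dim(d)[2L]
  if (T < 1L) stop("empty stack")
  gate <- if (config@scope == "single") T else config@gate
  if (gate > T) stop("gate (", gate, ") exceeds the number of frames (", T, ")")
  gs <- cpp_grouped_stat(d, H, W, T, as.integer(gate),
                         config@statistic == "median")
  G <- ncol(gs)
  if (G == 1L) {
    bg <- array(gs[, 1], dim = c(H, W, T))
  } else {
    t0 <- (seq_len(G) - 1L) * gate + 1L
    t1 <- pmin(T, seq_len(G) * gate)
    centers <- (t0 + t1) / 2
    tt <- pmin(pmax(seq_len(T), centers[1]), centers[G])
    Wm <- vapply(seq_len(G), function(g) {
      u <- numeric(G); u[g] <- 1
      splinefun(centers, u, method = "natural")(tt)
    }, numeric(T))
    bg <- array(gs %*% t(Wm), dim = c(H, W, T))
  }
  cpp_clamp0_inplace(bg)
  FrameStack(bg, pixelNm = stack@pixelNm, exposureMs = stack@exposureMs)
}

#' Subtract a background stack
#'
#' Elementwise subtraction; negative results are clamped at zero by default,
#' matching unsigned-integer image subtraction.
#'
#' @param stack,background \linkS4class{FrameStack}s of identical shape.
#' @param clampAtZero clamp negatives at zero.
#' @return A \linkS4class{FrameStack} (a plain array if clamping is off and
#'   negatives are present, counts stay signed inside an array attribute-free
#'   FrameStack is invalid, so the unclamped result is returned as an array).
#' @export
subtractBackground <- function(stack, background, clampAtZero = TRUE) {
  if (!identical(dim(stack@data), dim(background@data)))
    stop("stack shapes differ")
  out <- cpp_subtract(stack@data, background@data, clampAtZero)
  dim(out) <- dim(stack@data)
  if (clampAtZero)
    FrameStack(out, pixelNm = stack@pixelNm, exposureMs = stack@exposureMs)
  else out
}

#' Background-correct a movie
#'
#' Convenience composition: estimate the background with the configured
#' grouped projection, subtract it, clamp at zero.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param config a \linkS4class{CorrectionConfig} (default: moving median,
#'   gate 200).
#' @return List with \code{corrected} and \code{background}
#'   \linkS4class{FrameStack}s.
#' @export
correctStack <- function(stack, config = CorrectionConfig()) {
  bg <- estimateBackground(stack, config)
  corr <- subtractBackground(stack, bg, config@clampAtZero)
  if (!is(corr, "FrameStack"))
    corr <- FrameStack(pmax(corr, 0), pixelNm = stack@pixelNm,
                       exposureMs = stack@exposureMs)
  list(corrected = corr, background = bg)
}

#' Sweep the gate size of a moving correction
#'
#' Corrects the stack at each gate, reconstructs, and evaluates against the
#' ground-truth reconstruction, yielding one metric row per gate.
#'
#' @param stack the combined (signal + background) \linkS4class{FrameStack}.
#' @param gtTable ground-truth \linkS4class{LocalizationTable}.
#' @param gates integer vector of gates, each in [2, T].
#' @param statistic "median" or "mean".
#' @param gtImage optional ground-truth \linkS4class{RenderedImage} for the
#'   image-based coefficients.
#' @param detectionConfig,postprocessConfig pipeline parameters.
#' @param filter,drift passed to \code{\link{reconstruct}}.
#' @return data.frame with one row per gate: gate, percentEvents, meanCbc,
#'   meanNnd, manders, pearson.
#' @export
gateSweep <- function(stack, gtTable, gates = c(50, 100, 200, 500, 1000, 2000),
                      statistic = "median", gtImage = NULL,
                      detectionConfig = DetectionConfig(),
                      postprocessConfig = PostprocessConfig(),
                      filter = FALSE, drift = TRUE) {
  T <- nFrames(stack)
  bad <- gates < 2 | gates > T
  if (any(bad))
    stop("invalid gates: ", paste(gates[bad], collapse = ", "),
         " (must lie in [2, ", T, "])")
  rows <- lapply(gates, function(g) {
    cc <- correctStack(stack, CorrectionConfig("moving", statistic, gate = g))
    rec <- reconstruct(cc$corrected, detectionConfig, postprocessConfig,
                       filter = filter, drift = drift)
    rep <- evaluateReconstruction(gtTable, rec$table, gtImage, rec$image)
    data.frame(gate = g, percentEvents = rep@percentEvents,
               meanCbc = rep@meanCbc, meanNnd = rep@meanNnd,
               manders = rep@manders, pearson = rep@pearson)
  })
  do.call(rbind, rows)
}
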