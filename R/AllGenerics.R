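#' @rdname FrameStack-class
#' @param object,x a FrameStack / LocalizationTable.
#' @export
setGeneric("frameData", function(x) standardGeneric("frameData"))
#' @rdname FrameStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname FrameStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname FrameStack-class
#' @export
setGeneric("exposureTime", function(x) standardGeneric("exposureTime"))
#' @rdname LocalizationTable-class
#' @export
setGeneric("locData", function(x) standardGeneric("locData"))
#' @rdname LocalizationTable-class
#' @export
setGeneric("nLocalizations", function(x) standardGeneric("nLocalizations"))
#' @rdname LocalizationTable-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname FrameStack-class
#' @export
setMethod("frameData", "FrameStack", function(x) x@data)
#' @rdname FrameStack-class
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@data)[3L])
#' @rdname FrameStack-class
#' @export
setMethod("pixelSize", "FrameStack", function(x) x@pixelNm)
#' @rdname FrameStack-class
#' @export
setMethod("exposureTime", "FrameStack", function(x) x@exposureMs)
#' @rdname RenderedImage-class
#' @export
setMethod("pixelSize", "RenderedImage", function(x) x@pixelNm)

#' @rdname LocalizationTable-class
#' @export
setMethod("locData", "LocalizationTable", function(x) x@data)
#' @rdname LocalizationTable-class
#' @export
setMethod("nLocalizations", "LocalizationTable", function(x) nrow(x@data))
#' @rdname LocalizationTable-class
#' @export
setMethod("provenance", "LocalizationTable", function(x) x@provenance)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("FrameStack: %d frames of %d x %d px (%.0f nm/px, %.1f ms)\n",
              d[3], d[1], d[2], object@pixelNm, object@exposureMs))
  cat(sprintf("  counts: min %.1f, median %.1f, max %.1f\n",
              min(object@data), stats::median(object@data), max(object@data)))
})

setMethod("show", "LocalizationTable", function(object) {
  cat(sprintf("LocalizationTable (%s): %d localizations", object@provenance,
              nrow(object@data)))
  if (nrow(object@data) > 0)
    cat(sprintf(", frames %d-%d", min(object@data$frame),
                max(object@data$frame)))
  cat("\n")
})

setMethod("show", "EmitterSet", function(object) {
  cat(sprintf("EmitterSet '%s': %d emitters in a %d x %d px field (%.0f nm/px)\n",
              object@patternName, nrow(object@positions), object@fieldPx[1],
              object@fieldPx[2], object@pixelNm))
})

setMethod("show", "RenderedImage", function(object) {
  cat(sprintf("RenderedImage: %d x %d px at %.0f nm/px, total mass %.1f\n",
              nrow(object@data), ncol(object@data), object@pixelNm,
              sum(object@data)))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  cat(sprintf("  percent events : %.1f%%\n", object@percentEvents))
  cat(sprintf("  mean CBC       : %.3f\n", object@meanCbc))
  cat(sprintf("  mean NND       : %.3f nm\n", object@meanNnd))
  cat(sprintf("  Mander's       : %.3f\n", object@manders))
  cat(sprintf("  Pearson's      : %.3f\n", object@pearson))
})

setMethod("show", "CorrectionConfig", function(object) {
  cat(sprintf("CorrectionConfig: %s %s, gate %d, clamp %s\n", object@scope,
              object@statistic, object@gate, object@clampAtZero))
})
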