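#' FrameStack: a camera-count movie
#'
#' A T-frame grayscale movie held as an H x W x T array of nonnegative camera
#' counts, with the pixel pitch (nm) and exposure (ms) it was acquired or
#' simulated at. Every stage of the pipeline consumes and produces this
#' container. Row index is y, column index is x; a position \code{p} nm lies
#' in pixel \code{floor(p / pixelNm)} (origin at the top-left corner of pixel
#' (0,0)).
#'
#' @slot data numeric H x W x T array of counts.
#' @slot pixelNm pixel size in nanometres (default 100).
#' @slot exposureMs exposure time per frame in milliseconds (default 11).
#' @export
setClass("FrameStack",
  representation(data = "array", pixelNm = "numeric", exposureMs = "numeric"))

setValidity("FrameStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be an H x W x T array")
  if (any(d < 0, na.rm = TRUE)) return("counts must be nonnegative")
  if (length(object@pixelNm) != 1L || object@pixelNm <= 0)
    return("pixelNm must be a single positive number")
  if (length(object@exposureMs) != 1L || object@exposureMs <= 0)
    return("exposureMs must be a single positive number")
  TRUE
})

#' Construct a FrameStack
#'
#' @param data H x W x T array (or H x W matrix, taken as a single frame).
#' @param pixelNm pixel size in nm.
#' @param exposureMs exposure per frame in ms.
#' @return A \linkS4class{FrameStack}.
#' @examples
#' fs <- FrameStack(array(200, dim = c(8, 8, 4)))
#' nFrames(fs)
#' @export
FrameStack <- function(data, pixelNm = 100, exposureMs = 11) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  storage.mode(data) <- "double"
  new("FrameStack", data = data, pixelNm = pixelNm, exposureMs = exposureMs)
}

#' EmitterSet: ground-truth emitter positions
#'
#' Fluorophore positions (nm) arranged in one of the predefined test patterns
#' (radial star, dot array, parallel lines) within a field of
#' \code{fieldPx * pixelNm} nm on each axis.
#'
#' @slot positions n x 2 matrix of (x, y) in nm.
#' @slot patternName one of "star", "array", "lines".
#' @slot fieldPx integer length-2 field size in pixels.
#' @slot pixelNm pixel size in nm.
#' @export
setClass("EmitterSet",
  representation(positions = "matrix", patternName = "character",
                 fieldPx = "integer", pixelNm = "numeric"))

setValidity("EmitterSet", function(object) {
  p <- object@positions
  lim <- object@fieldPx * object@pixelNm
  if (ncol(p) != 2L) return("positions must be an n x 2 matrix")
  if (object@pixelNm <= 0) return("pixelNm must be positive")
  if (nrow(p) > 0 && (any(p[, 1] < 0 | p[, 1] >= lim[1]) ||
                      any(p[, 2] < 0 | p[, 2] >= lim[2])))
    return("all positions must lie inside the field")
  TRUE
})

#' Photophysics: the two-state blinking model
#'
#' Per-frame activation probability, geometric on-time, and a lognormal
#' brightness distribution for photons emitted per on-frame. The defaults
#' emulate an AF647-like dye under STORM buffer conditions: rare activation
#' (0.001 per frame), short on-times (mean 2 frames), broad brightness spread
#' around 2000 photons, and a 130 nm PSF standard deviation.
#'
#' @slot pOn per-frame activation probability per emitter.
#' @slot meanOnFrames expected on-duration in frames (geometric dwell).
#' @slot photonsMean expected photons per on-frame.
#' @slot photonsSdlog lognormal sdlog of the per-on-frame photon count
#'   (0 gives a fixed brightness).
#' @slot psfSigmaNm Gaussian PSF standard deviation in nm.
#' @export
setClass("Photophysics",
  representation(pOn = "numeric", meanOnFrames = "numeric",
                 photonsMean = "numeric", photonsSdlog = "numeric",
                 psfSigmaNm = "numeric"))

setValidity("Photophysics", function(object) {
  if (object@pOn <= 0 || object@pOn >= 1) return("pOn must be in (0, 1)")
  if (object@meanOnFrames < 1) return("meanOnFrames must be >= 1")
  if (object@photonsMean <= 0) return("photonsMean must be positive")
  if (object@photonsSdlog < 0) return("photonsSdlog must be >= 0")
  if (object@psfSigmaNm <= 50 || object@psfSigmaNm >= 200)
    return("psfSigmaNm must lie in (50, 200) nm")
  TRUE
})

#' @rdname Photophysics-class
#' @param pOn,meanOnFrames,photonsMean,photonsSdlog,psfSigmaNm see slots.
#' @return A \linkS4class{Photophysics}.
#' @export
Photophysics <- function(pOn = 0.001, meanOnFrames = 2, photonsMean = 2000,
                         photonsSdlog = 0.5, psfSigmaNm = 130) {
  new("Photophysics", pOn = pOn, meanOnFrames = meanOnFrames,
      photonsMean = photonsMean, photonsSdlog = photonsSdlog,
      psfSigmaNm = psfSigmaNm)
}

#' CameraModel: baseline offset and shot noise
#'
#' @slot baseline mean offset counts added to every pixel (default 200).
#' @slot poissonNoise whether to apply Poisson noise to the expected counts.
#' @export
setClass("CameraModel",
  representation(baseline = "numeric", poissonNoise = "logical"))

setValidity("CameraModel", function(object) {
  if (object@baseline < 0) return("baseline must be >= 0")
  TRUE
})

#' @rdname CameraModel-class
#' @param baseline,poissonNoise see slots.
#' @return A \linkS4class{CameraModel}.
#' @export
CameraModel <- function(baseline = 200, poissonNoise = TRUE) {
  new("CameraModel", baseline = baseline, poissonNoise = poissonNoise)
}

#' BackgroundSpec: structured background description
#'
#' A spatial pattern (uniform, dim/bright gradient, or multiple puncta) and a
#' temporal profile (constant, or decaying through five keyframes interpolated
#' by a monotone cubic). By default the background carries a frozen spatial
#' texture: one Poisson realisation of the pattern held fixed over time, the
#' granular appearance of an autofluorescence image. Amplitude is in camera
#' counts at the pattern peak; \code{NULL} picks the default multiple of the
#' brightest pixel of a single average rendered event (1x uniform,
#' 0.5x dim gradient, 10x bright gradient, 10x puncta).
#'
#' @slot spatial one of "uniform", "dim_gradient", "bright_gradient",
#'   "multiple_puncta".
#' @slot amplitude peak expected counts of the pattern.
#' @slot temporal "constant" or "decaying".
#' @slot keyframes five nonincreasing scale factors for the decaying profile.
#' @slot frozenTexture logical; add frozen shot-noise texture.
#' @slot fieldPx field size in pixels.
#' @slot pixelNm pixel size in nm.
#' @export
setClass("BackgroundSpec",
  representation(spatial = "character", amplitude = "numeric",
                 temporal = "character", keyframes = "numeric",
                 frozenTexture = "logical", fieldPx = "integer",
                 pixelNm = "numeric"))

setValidity("BackgroundSpec", function(object) {
  if (!object@spatial %in% c("uniform", "dim_gradient", "bright_gradient",
                             "multiple_puncta"))
    return("unknown spatial pattern")
  if (!object@temporal %in% c("constant", "decaying"))
    return("temporal must be 'constant' or 'decaying'")
  if (object@amplitude < 0) return("amplitude must be >= 0")
  if (object@temporal == "decaying") {
    k <- object@keyframes
    if (length(k) != 5L) return("decaying profile needs 5 keyframes")
    if (any(k < 0)) return("keyframes must be nonnegative")
    if (any(diff(k) > 0)) return("keyframes must be nonincreasing")
  }
  TRUE
})

#' @rdname BackgroundSpec-class
#' @param spatial,amplitude,temporal,keyframes,frozenTexture,fieldPx,pixelNm
#'   see slots.
#' @param photophysics used to derive the default amplitude.
#' @return A \linkS4class{BackgroundSpec}.
#' @export
BackgroundSpec <- function(spatial = "uniform", amplitude = NULL,
                           temporal = "constant",
                           keyframes = c(1.00, 0.55, 0.35, 0.27, 0.25),
                           frozenTexture = TRUE, fieldPx = c(180L, 180L),
                           pixelNm = 100, photophysics = Photophysics()) {
  if (is.null(amplitude)) {
    peak <- peakPixelExpectation(photophysics, pixelNm)
    amplitude <- switch(spatial,
      uniform = peak, dim_gradient = 0.5 * peak,
      bright_gradient = 10 * peak, multiple_puncta = 10 * peak,
      stop("unknown spatial pattern '", spatial, "'; valid patterns are ",
           "uniform, dim_gradient, bright_gradient, multiple_puncta"))
  }
  new("BackgroundSpec", spatial = spatial, amplitude = amplitude,
      temporal = temporal, keyframes = as.numeric(keyframes),
      frozenTexture = frozenTexture, fieldPx = as.integer(fieldPx),
      pixelNm = pixelNm)
}

#' CorrectionConfig: background-correction variant
#'
#' @slot scope "single" (one projection over the whole stack) or "moving"
#'   (consecutive gate-frame groups, cubically interpolated over time).
#' @slot statistic "median" or "mean".
#' @slot gate frames per group (default 200; forced to T for single scope).
#' @slot clampAtZero clamp negative corrected counts at zero (default TRUE),
#'   matching unsigned-integer image subtraction.
#' @export
setClass("CorrectionConfig",
  representation(scope = "character", statistic = "character",
                 gate = "integer", clampAtZero = "logical"))

setValidity("CorrectionConfig", function(object) {
  if (!object@scope %in% c("single", "moving"))
    return("scope must be 'single' or 'moving'")
  if (!object@statistic %in% c("median", "mean"))
    return("statistic must be 'median' or 'mean'")
  if (object@scope == "moving" && object@gate < 2L)
    return("gate must be >= 2")
  TRUE
})

#' @rdname CorrectionConfig-class
#' @param scope,statistic,gate,clampAtZero see slots.
#' @return A \linkS4class{CorrectionConfig}.
#' @export
CorrectionConfig <- function(scope = "moving", statistic = "median",
                             gate = 200L, clampAtZero = TRUE) {
  new("CorrectionConfig", scope = scope, statistic = statistic,
      gate = as.integer(gate), clampAtZero = clampAtZero)
}

#' DetectionConfig: wavelet pre-detection and fitting parameters
#'
#' @slot waveletOrder B-spline order of the a-trous filter (3).
#' @slot waveletScale wavelet scale (2); plane 2 supplies the maxima surface.
#' @slot thresholdMult threshold in SDs of the first wavelet plane (2).
#' @slot fitRadiusPx half-width of the square fit window in pixels (5).
#' @export
setClass("DetectionConfig",
  representation(waveletOrder = "integer", waveletScale = "integer",
                 thresholdMult = "numeric", fitRadiusPx = "integer"))

setValidity("DetectionConfig", function(object) {
  if (object@thresholdMult <= 0 || object@fitRadiusPx <= 0 ||
      object@waveletOrder <= 0 || object@waveletScale <= 0)
    return("all detection parameters must be positive")
  TRUE
})

#' @rdname DetectionConfig-class
#' @param waveletOrder,waveletScale,thresholdMult,fitRadiusPx see slots.
#' @return A \linkS4class{DetectionConfig}.
#' @export
DetectionConfig <- function(waveletOrder = 3L, waveletScale = 2L,
                            thresholdMult = 2, fitRadiusPx = 5L) {
  new("DetectionConfig", waveletOrder = as.integer(waveletOrder),
      waveletScale = as.integer(waveletScale), thresholdMult = thresholdMult,
      fitRadiusPx = as.integer(fitRadiusPx))
}

#' PostprocessConfig: merging, drift correction and rendering parameters
#'
#' @slot mergeRadiusNm reblink merge radius (40 nm).
#' @slot mergeFrames maximal frame gap for merging (20).
#' @slot driftBins temporal bins for cross-correlation drift correction (3).
#' @slot driftMag rendering magnification for drift estimation (5).
#' @slot renderMag final rendering magnification (10, i.e. 10 nm pixels).
#' @export
setClass("PostprocessConfig",
  representation(mergeRadiusNm = "numeric", mergeFrames = "integer",
                 driftBins = "integer", driftMag = "integer",
                 renderMag = "integer"))

setValidity("PostprocessConfig", function(object) {
  v <- c(object@mergeRadiusNm, object@mergeFrames, object@driftBins,
         object@driftMag, object@renderMag)
  if (any(v <= 0)) return("all postprocessing parameters must be positive")
  TRUE
})

#' @rdname PostprocessConfig-class
#' @param mergeRadiusNm,mergeFrames,driftBins,driftMag,renderMag see slots.
#' @return A \linkS4class{PostprocessConfig}.
#' @export
PostprocessConfig <- function(mergeRadiusNm = 40, mergeFrames = 20L,
                              driftBins = 3L, driftMag = 5L,
                              renderMag = 10L) {
  new("PostprocessConfig", mergeRadiusNm = mergeRadiusNm,
      mergeFrames = as.integer(mergeFrames), driftBins = as.integer(driftBins),
      driftMag = as.integer(driftMag), renderMag = as.integer(renderMag))
}

#' LocalizationTable: per-event records
#'
#' One row per localization: frame index, position (nm), intensity (photons),
#' and — for fitted reconstructions — PSF sigma (nm), lateral uncertainty (nm)
#' and local offset (counts). Both ground-truth and test reconstructions use
#' this container; \code{provenance} records which.
#'
#' @slot data data.frame with columns \code{frame, x, y, intensity} and
#'   optionally \code{sigma, uncertainty, offset}.
#' @slot provenance "ground_truth", "reconstruction" or "generative".
#' @export
setClass("LocalizationTable",
  representation(data = "data.frame", provenance = "character"))

setValidity("LocalizationTable", function(object) {
  d <- object@data
  need <- c("frame", "x", "y", "intensity")
  miss <- setdiff(need, names(d))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(d) > 0) {
    if (any(d$frame < 0)) return("frame must be >= 0")
    if ("sigma" %in% names(d) && any(d$sigma <= 0, na.rm = TRUE))
      return("sigma must be positive")
    if ("uncertainty" %in% names(d) && any(d$uncertainty <= 0, na.rm = TRUE))
      return("uncertainty must be positive")
  }
  if (!object@provenance %in% c("ground_truth", "reconstruction", "generative"))
    return("provenance must be ground_truth, reconstruction or generative")
  TRUE
})

#' @rdname LocalizationTable-class
#' @param data data.frame of localization rows.
#' @param provenance record origin.
#' @return A \linkS4class{LocalizationTable}.
#' @export
LocalizationTable <- function(data, provenance = "reconstruction") {
  new("LocalizationTable", data = as.data.frame(data), provenance = provenance)
}

#' RenderedImage: a super-resolved intensity grid
#'
#' @slot data nonnegative matrix at \code{pixelNm} spacing.
#' @slot pixelNm rendered pixel size in nm (10 nm at default magnification).
#' @export
setClass("RenderedImage",
  representation(data = "matrix", pixelNm = "numeric"))

setValidity("RenderedImage", function(object) {
  if (any(object@data < 0)) return("rendered intensities must be nonnegative")
  if (object@pixelNm <= 0) return("pixelNm must be positive")
  TRUE
})

#' @rdname RenderedImage-class
#' @param data matrix of intensities.
#' @param pixelNm rendered pixel size (nm).
#' @return A \linkS4class{RenderedImage}.
#' @export
RenderedImage <- function(data, pixelNm = 10) {
  new("RenderedImage", data = data, pixelNm = pixelNm)
}

#' MetricReport: the five restoration statistics
#'
#' Agreement of a test reconstruction with a ground truth: percent of events
#' detected, coordinate-based colocalization (mean and 0.1-wide histogram),
#' nearest neighbour distance (mean and histogram), Mander's overlap and
#' Pearson correlation of the rendered image pair.
#'
#' @slot percentEvents percent of ground-truth event count (may exceed 100).
#' @slot meanCbc mean coordinate-based colocalization, in [-1, 1].
#' @slot cbcHist counts in 0.1-wide bins over [-1, 1]; sums to event count.
#' @slot meanNnd mean nearest neighbour distance (nm).
#' @slot nndHist counts in fine bins (0.1 nm, overflow in the last bin).
#' @slot manders Mander's overlap coefficient of the rendered pair, [0, 1].
#' @slot pearson Pearson correlation of the rendered pair, [-1, 1].
#' @export
setClass("MetricReport",
  representation(percentEvents = "numeric", meanCbc = "numeric",
                 cbcHist = "numeric", meanNnd = "numeric",
                 nndHist = "numeric", manders = "numeric",
                 pearson = "numeric"))
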