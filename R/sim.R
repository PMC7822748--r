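#' Brightest expected pixel of a single average event
#'
#' The expected count in the central pixel of an integrated Gaussian spot of
#' \code{photonsMean} photons centred on a pixel. Background amplitudes are
#' expressed relative to this reference.
#'
#' @param photophysics a \linkS4class{Photophysics}.
#' @param pixelNm pixel size in nm.
#' @return Expected counts in the brightest pixel.
#' @export
peakPixelExpectation <- function(photophysics = Photophysics(), pixelNm = 100) {
  s <- photophysics@psfSigmaNm / pixelNm
  f <- erf(0.5 / (s * sqrt(2)))
  photophysics@photonsMean * f * f
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Generate a ground-truth emitter pattern
#'
#' Lays emitters out as a radial star (8 spokes, 20 nm site spacing), a square
#' lattice of 4-emitter clusters, or 6 parallel lines (40 nm site spacing).
#' The emitter count is solved from the target mean blinking-event density
#' (events per frame) under the stationary on-state occupancy of the
#' photophysics model; emitters are assigned to sites cyclically (several
#' labels per site for dense patterns) with a small labelling jitter.
#'
#' @param patternName "star", "array" or "lines".
#' @param densityTarget target mean events per frame (reference densities:
#'   star 68.8, array 3.8, lines 19.9 in the full 180 x 180 px field).
#' @param photophysics a \linkS4class{Photophysics}; sets the occupancy.
#' @param fieldPx field size in pixels.
#' @param pixelNm pixel size in nm.
#' @param jitterNm SD of the normal labelling jitter applied per emitter.
#' @param seed optional RNG seed.
#' @return An \linkS4class{EmitterSet}.
#' @examples
#' es <- generatePattern("array", 3.8, seed = 1)
#' es
#' @export
generatePattern <- function(patternName, densityTarget,
                            photophysics = Photophysics(),
                            fieldPx = c(180L, 180L), pixelNm = 100,
                            jitterNm = 8, seed = NULL) {
  if (!patternName %in% c("star", "array", "lines"))
    stop("unknown pattern '", patternName,
         "'; valid patterns are star, array, lines")
  if (densityTarget <= 0) stop("densityTarget must be positive")
  if (!is.null(seed)) set.seed(seed)
  lim <- fieldPx * pixelNm
  ctr <- lim / 2
  occ <- photophysics@pOn / (photophysics@pOn + 1 / photophysics@meanOnFrames)
  n <- max(1L, as.integer(round(densityTarget / occ)))
  margin <- 600
  sites <- switch(patternName,
    star = {
      rmax <- min(ctr) - margin
      r <- seq(60, rmax, by = 20)
      ang <- (0:7) * pi / 4
      do.call(rbind, lapply(ang, function(a)
        cbind(ctr[1] + r * cos(a), ctr[2] + r * sin(a))))
    },
    array = {
      g <- seq(margin + 900, lim[1] - margin - 900, length.out = 12)
      off <- 40 * cbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1)) / 2
      lattice <- as.matrix(expand.grid(g, g))
      do.call(rbind, lapply(seq_len(nrow(lattice)), function(i)
        sweep(off, 2, lattice[i, ], "+")))
    },
    lines = {
      xs <- seq(margin + 1200, lim[1] - margin - 1200, length.out = 6)
      ys <- seq(margin, lim[2] - margin, by = 40)
      as.matrix(expand.grid(xs, ys))
    })
  idx <- (seq_len(n) - 1L) %% nrow(sites) + 1L
  pos <- sites[idx, , drop = FALSE]
  if (jitterNm > 0)
    pos <- pos + matrix(stats::rnorm(2 * n, sd = jitterNm), ncol = 2)
  pos[, 1] <- pmin(pmax(pos[, 1], 0), lim[1] - 1e-6)
  pos[, 2] <- pmin(pmax(pos[, 2], 0), lim[2] - 1e-6)
  dimnames(pos) <- list(NULL, c("x", "y"))
  new("EmitterSet", positions = pos, patternName = patternName,
      fieldPx = as.integer(fieldPx), pixelNm = pixelNm)
}

#' Simulate stochastic blinking
#'
#' Runs the two-state blinking model over the emitter set: activation with
#' probability \code{pOn} per frame, geometric on-dwell with the configured
#' mean, lognormal photons per on-frame. Emitters start in the stationary
#' state so the event density is homogeneous in time.
#'
#' @param emitters an \linkS4class{EmitterSet}.
#' @param photophysics a \linkS4class{Photophysics}.
#' @param nFrames number of frames to simulate.
#' @param seed optional RNG seed; the same seed gives an identical table.
#' @return A \linkS4class{LocalizationTable} (provenance "generative") with
#'   columns frame, x, y, intensity.
#' @examples
#' es <- generatePattern("array", 3.8, seed = 1)
#' tt <- simulateBlinking(es, nFrames = 100, seed = 2)
#' nLocalizations(tt) / 100   # close to 3.8 events per frame
#' @export
simulateBlinking <- function(emitters, photophysics = Photophysics(),
                             nFrames, seed = NULL) {
  stopifnot(nFrames >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- emitters@positions
  if (nrow(p) == 0) {
    return(LocalizationTable(data.frame(frame = integer(), x = numeric(),
                                        y = numeric(), intensity = numeric()),
                             provenance = "generative"))
  }
  meanlog <- log(photophysics@photonsMean) - photophysics@photonsSdlog^2 / 2
  m <- cpp_simulate_blinking(p[, 1], p[, 2], as.integer(nFrames),
                             photophysics@pOn, photophysics@meanOnFrames,
                             meanlog, photophysics@photonsSdlog)
  d <- data.frame(frame = as.integer(m[, 1]), x = m[, 2], y = m[, 3],
                  intensity = m[, 4])
  d <- d[order(d$frame), , drop = FALSE]
  rownames(d) <- NULL
  LocalizationTable(d, provenance = "generative")
}

#' Render a generative truth table into a movie
#'
#' Each event deposits an integrated 2-D Gaussian (error function over pixel
#' edges) of its photon count; the camera baseline is added and, if the camera
#' model says so, one Poisson draw per pixel per frame is applied to the total
#' expectation.
#'
#' @param truth a generative \linkS4class{LocalizationTable}.
#' @param camera a \linkS4class{CameraModel}.
#' @param psfSigmaNm PSF standard deviation (nm).
#' @param nFrames frames in the output stack (defaults to the last frame).
#' @param fieldPx,pixelNm field geometry.
#' @param exposureMs exposure metadata carried on the stack.
#' @return A \linkS4class{FrameStack}.
#' @export
renderFrames <- function(truth, camera = CameraModel(), psfSigmaNm = 130,
                         nFrames = NULL, fieldPx = c(180L, 180L),
                         pixelNm = 100, exposureMs = 11) {
  d <- locData(truth)
  if (is.null(nFrames)) nFrames <- if (nrow(d)) max(d$frame) else 1L
  H <- fieldPx[2]; W <- fieldPx[1]
  if (4.5 * psfSigmaNm / pixelNm > min(H, W))
    stop("PSF is wider than the field")
  stack <- array(0, dim = c(H, W, as.integer(nFrames)))
  if (nrow(d))
    cpp_render_events(stack, H, W, as.integer(nFrames), as.integer(d$frame),
                      d$x, d$y, d$intensity, psfSigmaNm, pixelNm)
  stack <- stack + camera@baseline
  if (camera@poissonNoise) cpp_poisson_inplace(stack)
  FrameStack(stack, pixelNm = pixelNm, exposureMs = exposureMs)
}

#' Build a structured background stack
#'
#' Realises the spatial pattern at the configured amplitude, optionally
#' freezes one Poisson draw of it as static texture, and extends it over time
#' either constantly or along a decaying profile: a monotone cubic through the
#' five keyframes placed evenly over the stack (so the profile plateaus toward
#' the last keyframe), evaluated at every frame.
#'
#' @param spec a \linkS4class{BackgroundSpec}.
#' @param nFrames frames to generate.
#' @param seed optional RNG seed (texture and puncta placement).
#' @param exposureMs exposure metadata.
#' @return A \linkS4class{FrameStack}.
#' @examples
#' bg <- makeBackground(BackgroundSpec("uniform", amplitude = 50,
#'                                     frozenTexture = FALSE), nFrames = 3)
#' all(frameData(bg) == 50)
#' @export
makeBackground <- function(spec, nFrames, seed = NULL, exposureMs = 11) {
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)
  H <- spec@fieldPx[2]; W <- spec@fieldPx[1]
  a <- spec@amplitude
  xg <- (seq_len(W) - 0.5) / W
  pat <- switch(spec@spatial,
    uniform = matrix(a, H, W),
    dim_gradient = matrix(a * xg, H, W, byrow = TRUE),
    bright_gradient = matrix(a * xg, H, W, byrow = TRUE),
    multiple_puncta = {
      base <- matrix(0.05 * a, H, W)
      nb <- 30L
      cx <- stats::runif(nb, 0.05, 0.95) * W
      cy <- stats::runif(nb, 0.05, 0.95) * H
      sg <- stats::runif(nb, 300, 600) / spec@pixelNm
      amp <- a * stats::runif(nb, 0.3, 1)
      col <- matrix(seq_len(W), H, W, byrow = TRUE)
      row <- matrix(seq_len(H), H, W)
      for (i in seq_len(nb)) {
        base <- base + amp[i] *
          exp(-((col - cx[i])^2 + (row - cy[i])^2) / (2 * sg[i]^2))
      }
      base
    })
  tex <- if (spec@frozenTexture) {
    matrix(rpois(length(pat), pat), H, W)
  } else pat
  scale <- temporalProfile(spec, nFrames)
  stack <- array(as.vector(tex) %o% scale, dim = c(H, W, nFrames))
  FrameStack(stack, pixelNm = spec@pixelNm, exposureMs = exposureMs)
}

#' Temporal scale profile of a background spec
#'
#' Constant profiles return 1 for every frame; decaying profiles return the
#' monotone (Hyman-filtered) cubic through the keyframes, knots placed evenly
#' from the first to the last frame.
#'
#' @param spec a \linkS4class{BackgroundSpec}.
#' @param nFrames number of frames.
#' @return Numeric vector of per-frame scale factors, length \code{nFrames}.
#' @export
temporalProfile <- function(spec, nFrames) {
  if (spec@temporal == "constant") return(rep(1, nFrames))
  knots <- seq(1, nFrames, length.out = length(spec@keyframes))
  f <- splinefun(knots, spec@keyframes, method = "hyman")
  f(seq_len(nFrames))
}

#' Sum two stacks
#'
#' Elementwise sum; the standard way to compose a noisy simulated signal stack
#' with a deterministic background stack, mirroring how validation data are
#' assembled (the background carries no temporal noise of its own).
#'
#' @param signal,background \linkS4class{FrameStack}s of identical shape and
#'   metadata.
#' @return A \linkS4class{FrameStack}.
#' @export
combineStacks <- function(signal, background) {
  if (!identical(dim(signal@data), dim(background@data)))
    stop("stack shapes differ")
  if (signal@pixelNm != background@pixelNm)
    stop("pixel sizes differ")
  FrameStack(signal@data + background@data, pixelNm = signal@pixelNm,
             exposureMs = signal@exposureMs)
}
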