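#' Write a movie stack as multi-page 16-bit TIFF
#'
#' Counts are stored as 16-bit unsigned integers; pixel size and exposure go
#' to a YAML sidecar next to the TIFF so the round trip preserves metadata.
#'
#' @param stack a \linkS4class{FrameStack} (counts must fit in 16 bits).
#' @param path output .tif path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  d <- stack@data
  if (max(d) > 65535) stop("counts exceed the 16-bit range")
  pages <- lapply(seq_len(dim(d)[3L]), function(t) round(d[, , t]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(pixel_nm = stack@pixelNm,
                        exposure_ms = stack@exposureMs),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a movie stack from a multi-page TIFF
#'
#' Accepts 8/16/32-bit grayscale pages. Metadata come from the YAML sidecar
#' written by \code{\link{writeStack}}; without one, the defaults (100 nm
#' pixels, 11 ms exposure) are applied with a warning.
#'
#' @param path .tif path.
#' @return A \linkS4class{FrameStack}.
#' @export
readStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  if (!bits %in% c(8L, 16L, 32L))
    stop("unsupported bit depth: ", bits)
  if (length(dim(pages[[1]])) != 2L)
    stop("expected single-channel grayscale pages")
  scale <- if (bits == 32L) 1 else 2^bits - 1
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  arr <- array(0, dim = c(H, W, length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- round(pages[[t]] * scale)
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    FrameStack(arr, pixelNm = meta$pixel_nm, exposureMs = meta$exposure_ms)
  } else {
    warning("no metadata sidecar; assuming 100 nm pixels, 11 ms exposure")
    FrameStack(arr, pixelNm = 100, exposureMs = 11)
  }
}

#' Write a rendered image as 32-bit float TIFF
#'
#' @param img a \linkS4class{RenderedImage}.
#' @param path output .tif path.
#' @return \code{path}, invisibly.
#' @export
writeRendered <- function(img, path) {
  tiff::writeTIFF(img@data / max(img@data, 1e-12), path,
                  bits.per.sample = 32L)
  yaml::write_yaml(list(pixel_nm = img@pixelNm, scale = max(img@data, 1e-12)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a rendered image written by \code{\link{writeRendered}}
#'
#' @param path .tif path.
#' @return A \linkS4class{RenderedImage}.
#' @export
readRendered <- function(path) {
  m <- tiff::readTIFF(path)
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    RenderedImage(m * meta$scale, pixelNm = meta$pixel_nm)
  } else {
    warning("no metadata sidecar; assuming 10 nm pixels, unit scale")
    RenderedImage(m, pixelNm = 10)
  }
}

.tsColumns <- c(frame = "frame", x = "x [nm]", y = "y [nm]",
                sigma = "sigma [nm]", intensity = "intensity [photon]",
                offset = "offset [photon]", uncertainty = "uncertainty_xy [nm]")

#' Write a localization table as CSV
#'
#' ThunderSTORM-compatible header (\code{frame, x [nm], y [nm], sigma [nm],
#' intensity [photon], offset [photon], uncertainty_xy [nm]}); columns the
#' table lacks are omitted.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param path output .csv path.
#' @return \code{path}, invisibly.
#' @export
writeLocalizations <- function(table, path) {
  d <- locData(table)
  keep <- intersect(names(.tsColumns), names(d))
  out <- d[, keep, drop = FALSE]
  names(out) <- .tsColumns[keep]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a localization table from CSV
#'
#' Accepts the ThunderSTORM header or bare/underscore dialects
#' (\code{x_nm}, \code{x}, ...), normalising them with a message. Rows with
#' unparseable coordinates are skipped and counted.
#'
#' @param path .csv path.
#' @param provenance provenance tag for the table.
#' @return A \linkS4class{LocalizationTable}.
#' @export
readLocalizations <- function(path, provenance = "reconstruction") {
  d <- read.csv(path, check.names = FALSE)
  nm <- names(d)
  canon <- function(s) {
    s <- tolower(gsub("\\s*\\[.*\\]", "", s))
    s <- gsub("_nm$|_photon$|_xy$", "", gsub("uncertainty_xy", "uncertainty", s))
    s
  }
  mapped <- canon(nm)
  if (!identical(nm, unname(.tsColumns[mapped])) &&
      any(nm != mapped))
    message("normalised foreign header dialect: ",
            paste(nm, collapse = ", "))
  names(d) <- mapped
  need <- c("frame", "x", "y", "intensity")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  for (cn in intersect(names(.tsColumns), names(d)))
    d[[cn]] <- suppressWarnings(as.numeric(d[[cn]]))
  bad <- !stats::complete.cases(d[, need])
  if (any(bad)) message("skipped ", sum(bad), " malformed rows")
  LocalizationTable(d[!bad, , drop = FALSE], provenance = provenance)
}

#' Read a YAML run configuration
#'
#' Blocks: \code{pattern} (name, density), \code{photophysics},
#' \code{camera}, \code{background}, \code{correction}, \code{seed},
#' \code{n_frames}. Missing blocks fall back to package defaults; unknown
#' values fail validation before any computation.
#'
#' @param path .yaml path.
#' @return Named list of constructed configuration objects.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(Photophysics, utils::modifyList(list(), y$photophysics %||% list()))
  cam <- do.call(CameraModel, y$camera %||% list())
  bg <- if (!is.null(y$background))
    do.call(BackgroundSpec, c(y$background, list(photophysics = ph))) else NULL
  corr <- do.call(CorrectionConfig, y$correction %||% list())
  list(pattern = y$pattern$name %||% "star",
       density = y$pattern$density %||% 68.8,
       photophysics = ph, camera = cam, background = bg, correction = corr,
       seed = as.integer(y$seed %||% 1L),
       nFrames = as.integer(y$n_frames %||% 10000L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
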