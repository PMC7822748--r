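# Small in-code fixtures shared across the suite. Everything is generated at
# test time; sizes are kept small so the full suite stays fast.

# One-event frame rendered through the package's own renderer (noiseless by
# default so oracles are exact).
spotFrame <- function(xNm, yNm, photons = 2000, sigmaNm = 130, baseline = 5,
                      fieldPx = 32, noise = FALSE, frame = 1L) {
  tab <- LocalizationTable(
    data.frame(frame = frame, x = xNm, y = yNm, intensity = photons),
    provenance = "generative")
  fs <- renderFrames(tab, CameraModel(baseline, poissonNoise = noise),
                     sigmaNm, nFrames = frame, fieldPx = c(fieldPx, fieldPx))
  frameData(fs)[, , frame]
}

# Independent a-trous decomposition used as the detection oracle: plain R
# convolution with replicate padding.
oracleWavelet <- function(img) {
  k <- c(1, 4, 6, 4, 1) / 16
  convRep <- function(m, kernel, step) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(0, H, W)
    for (r in seq_len(H)) for (c in seq_len(W)) {
      s <- 0
      for (j in -2:2) {
        rr <- min(max(r + j * step, 1), H)
        s <- s + kernel[j + 3] * m[rr, c]
      }
      out[r, c] <- s
    }
    out2 <- matrix(0, H, W)
    for (r in seq_len(H)) for (c in seq_len(W)) {
      s <- 0
      for (j in -2:2) {
        cc <- min(max(c + j * step, 1), W)
        s <- s + kernel[j + 3] * out[r, cc]
      }
      out2[r, c] <- s
    }
    out2
  }
  V1 <- convRep(img, k, 1)
  V2 <- convRep(V1, k, 2)
  list(W1 = img - V1, W2 = V1 - V2)
}

# A small blinking data set on a sparse pattern; used by several pipeline
# tests.
smallDataset <- function(pattern = "array", density = 3.8, background = NULL,
                         nFrames = 120L, seed = 42L) {
  simulateDataset(pattern, density, background, nFrames, seed = seed)
}

randomTable <- function(n, lim = 18000, seed = 1, frames = 100L) {
  set.seed(seed)
  LocalizationTable(data.frame(frame = sample.int(frames, n, replace = TRUE),
                               x = runif(n, 0, lim), y = runif(n, 0, lim),
                               intensity = rlnorm(n, log(2000), 0.5)))
}
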