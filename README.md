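# stormDefog

Temporal median background correction for single-molecule localization
microscopy (STORM/SMLM), with the simulation, localization and evaluation
machinery to validate it end-to-end.

## The problem

STORM reconstructs nanoscale images from movies of stochastically blinking
fluorophores. Highly autofluorescent samples — tissue macrophages are the
canonical case — superimpose a bright, spatially structured background that
is stable in time, drowning the blinks and corrupting reconstruction. Because
the signal is temporally sparse while the background is temporally stable,
the two can be separated along the time axis.

For a movie `I(x, y, t)` the background estimate is, per pixel,

```
B(x, y, t) = resize_t( median{ I(x, y, t') : t' in gate g }, g = 1..G )
```

the median (or mean) over consecutive non-overlapping gate-frame blocks
(default gate = 200), cubically interpolated back over the frame index, and
the corrected movie is `max(I - B, 0)`. The median's 50% breakdown value
makes it insensitive to blink outliers, so the *moving median* variant tracks
slowly decaying autofluorescence without absorbing signal — the recommended
correction. The package also provides the reference pipeline around it:
blinking-fluorophore simulation with structured backgrounds, wavelet
detection plus integrated-Gaussian maximum-likelihood fitting, reblink
merging, cross-correlation drift correction, average-shifted-histogram
rendering, the five restoration metrics (percent events, coordinate-based
colocalization, nearest neighbour distance, Mander's overlap, Pearson
correlation), and downstream quantification of nanoscale CD81-style ring
structures and membrane-marker coverage.

## Worked example

Simulate a line-patterned ground truth, bury it under a decaying
autofluorescence-like gradient, correct, and evaluate:

```r
library(stormDefog)
set.seed(1)
emitters <- generatePattern("lines", densityTarget = 19.9)
truth    <- simulateBlinking(emitters, nFrames = 2000)
gtStack  <- renderFrames(truth, CameraModel(baseline = 200), psfSigmaNm = 130,
                         nFrames = 2000)
bg       <- makeBackground(BackgroundSpec("bright_gradient"), nFrames = 2000)
movie    <- combineStacks(gtStack, bg)

corr     <- correctStack(movie, CorrectionConfig("moving", "median", gate = 200))
recGT    <- reconstruct(correctStack(gtStack, CorrectionConfig())$corrected,
                        filter = FALSE)
rec      <- reconstruct(corr$corrected, filter = FALSE)
evaluateReconstruction(recGT$table, rec$table, recGT$image, rec$image)
```

```
MetricReport
  percent events : 100.0%
  mean CBC       : 0.999
  mean NND       : 0.118 nm
  Mander's       : 0.995
  Pearson's      : 0.995
```

Read: after moving-median correction the reconstruction recovers the
ground-truth event count (percent events ~100%), every ground-truth event has
a corrected counterpart essentially on top of it (mean nearest neighbour
distance far below the ~20 nm resolution of the technique), and the rendered
10 nm-pixel images co-occur almost perfectly (CBC, Mander's and Pearson's
near 1). Running `reconstruct(movie, filter = FALSE, cameraOffset = 200)`
without correction instead detects only ~76% of the events and the image
coefficients collapse (Mander's ~0.07), which is the problem the filter
exists to solve.

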