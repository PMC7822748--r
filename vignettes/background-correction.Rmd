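---
title: "Temporal median background correction for SMLM: model, simulator and validation design"
author: "stormDefog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal median background correction for SMLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stormDefog)
```

## The problem

Single-molecule localization microscopy (STORM/PALM) reconstructs
super-resolved images from thousands of movie frames in which individual
fluorophores blink stochastically. The useful signal is therefore *temporally
sparse*: any one pixel holds an emitter's light in only a small fraction of
frames. Cellular autofluorescence — severe in tissue macrophages — behaves in
the opposite way: it is bright, structured, and *temporally stable*, decaying
only slowly under illumination. Conventional spatial filtering cannot separate
the two, but their temporal signatures can.

`stormDefog` implements the correction that exploits this: per pixel, a
grouped temporal projection (median or mean over consecutive `gate`-frame
blocks) estimates the background, the group images are interpolated back to
one background frame per movie frame with a cubic through the group-centre
times, and the estimate is subtracted (clamped at zero, matching
unsigned-integer image arithmetic). The moving median with a 200-frame gate is
the recommended variant.

Why the median: a blinking event is a large-amplitude outlier in a pixel's
time series. The median of a window is unaffected until more than half the
window is contaminated (breakdown value 50%), whereas a single blink already
biases the mean. `estimateBackground()` keeps full float precision throughout;
the even-window median is the mean of the two central order statistics.

Two properties of the grouped median matter for validation and are covered by
tests:

* **Shift equivariance.** For a background that is constant within each gate
  window, `median(signal + bg) = median(signal) + bg` exactly. Correction
  therefore removes a temporally constant background *perfectly*, whatever its
  spatial structure.
* **Breakdown exactness.** If every gate window of every pixel has event
  signal in strictly fewer than half its frames, the estimated background
  equals the noise-free background exactly on constructed stacks.

## The simulator and what it emulates

The validation machinery regenerates everything synthetically:

* **Patterns.** `generatePattern()` arranges emitters as an 8-spoke radial
  star (20 nm site spacing), a square lattice of 4-emitter clusters, or six
  parallel lines (40 nm spacing), in a 180 x 180 px field at 100 nm pixels.
  Emitter counts are solved from the target blinking-event density (events per
  frame: star 68.8, array 3.8, lines 19.9) given the stationary on-state
  occupancy, with several labels per structural site where needed and a small
  (8 nm) labelling jitter.
* **Photophysics.** A two-state model: activation probability 0.001 per frame
  per emitter, geometric on-dwell with mean 2 frames, and *lognormal* photons
  per on-frame (mean 2000, sdlog 0.5). The brightness spread matters: real
  dye populations (and the reference simulations this package emulates) span
  dim to bright events, so detection degrades *gradually* as background noise
  raises the threshold. A fixed brightness would switch detection all-or-nothing
  and could not reproduce intermediate detection percentages. PSF sigma is
  130 nm, rendered as an integrated Gaussian (error function over pixel
  edges); the camera adds a baseline of 200 counts and a single Poisson draw
  per pixel.
* **Backgrounds.** Four spatial patterns — uniform, dim gradient (0.5x the
  brightest pixel of an average event), bright gradient (10x), multiple
  puncta (10x blobs of 300-600 nm) — with either a constant temporal profile
  or a decaying one: a monotone cubic through five nonincreasing keyframes
  (default 1.00, 0.55, 0.35, 0.27, 0.25) spread over the stack, emulating the
  slowing photobleaching of autofluorescence that plateaus mid-acquisition.
  By default the background carries **frozen texture**: one Poisson
  realisation of the pattern, held fixed over time and scaled by the decay
  profile. This is the decisive feature of an autofluorescence image — grainy
  in space, stable in time. A spatially smooth ramp would be invisible to the
  band-pass wavelet detector and would not perturb reconstruction at all;
  the frozen grain is exactly what inflates the detection threshold in
  uncorrected data and exactly what a temporal median removes.
* **Composition.** Validation movies are the noisy ground-truth stack plus
  the *deterministic* background stack (`combineStacks()`). The background
  adds no temporal noise of its own, so the correction's task is exactly to
  remove it; `renderFrames()` can instead draw Poisson noise on a combined
  expectation when a physically noisy composition is wanted.

What the simulator does **not** model: EMCCD gain and read noise, astigmatic
3-D PSFs, dipole orientation effects, stage drift (available only as an
explicit injection in tests), and the frame-to-frame flicker of real
autofluorescence. Passing tests therefore demonstrate correctness of the
algorithms and faithful restoration under these idealised conditions, not
performance on any particular instrument's data.

## The localization pipeline

`reconstruct()` chains the stages with the standard parameters throughout:

1. **Camera offset.** The configured baseline is subtracted (clamped at zero)
   before analysis so fitting sees photon-scale data. Corrected stacks pass 0
   here — their baseline was already removed with the background. Analysing
   one data set with its offset and the other without would bias the
   comparison: the Poisson-likelihood weighting depends on the local mean.
2. **Detection.** B-spline a-trous wavelets (order 3, scale 2); candidates
   are 8-connected maxima of the second wavelet plane above 2 standard
   deviations of the first plane, recomputed per frame (which adapts the
   threshold to decaying backgrounds). Plateau ties go to the lowest
   (row, col).
3. **Fitting.** Integrated symmetric Gaussian plus constant offset, maximum
   Poisson likelihood over an 11 x 11 window (Fisher scoring, step damping,
   50-iteration cap, 1e-6 relative tolerance; initialisation: window
   centroid, sigma 1.3 px, window minimum as offset). Edge candidates without
   a full window are dropped, as are non-converged fits. The per-event
   uncertainty is the Thompson/Mortensen precision.
4. **Filtering** (experimental data only): intensity > 500 photons,
   50 < sigma < 200 nm, uncertainty < 30 nm, all strict. Simulated
   validation data are not filtered, mirroring how such data are processed.
5. **Merging.** Reblinks within 40 nm and 20 frames are chained greedily in
   frame order against the track's photon-weighted running centroid (the
   40 nm/20 frame rule does not itself specify chaining; the greedy
   running-centroid rule is documented so results are reproducible).
6. **Drift correction.** Three temporal bins rendered at 5x magnification,
   registered to the first bin by the cross-correlation peak with parabolic
   subpixel refinement; shifts interpolate linearly between bin centres and
   extend flat at the ends (three bins under-determine anything
   higher-order). Bin histograms are blurred with a 5-tap B-spline kernel
   (about 26 nm) first: at 20 nm render pitch two disjoint-time renders of
   the same structure share almost no identical pixels, and the blur makes
   the correlation peak robust to fit jitter.
7. **Rendering.** Average shifted histogram at 10 nm pixels (2 x 2 lattice of
   half-pixel shifts); total mass equals the number of rows exactly.

## Restoration metrics and the reference definition

`evaluateReconstruction()` reports: percent of ground-truth events detected,
coordinate-based colocalization (CBC; per ground-truth event, Spearman rank
correlation between the area-normalised cumulative neighbour profiles of the
two point sets over ten 50 nm annuli up to 500 nm, damped by
`exp(-d_nearest/500)`), nearest neighbour distances (ground truth to test),
Mander's overlap and Pearson correlation of the rendered image pair. All
comparisons are referenced ground truth to test. Conventions: the reference
point is not its own neighbour, and an exactly zero-distance match in the
other channel is treated as the event's own image — this keeps the two
channels symmetric, so self-comparison scores exactly 1. Events with no
neighbours in either channel score 0. CBC carries a small positive bias for
sparse point sets (both radial profiles then share the discrete 1/r^2 decay
of their first neighbour) and near field edges; the randomisation test is run
in the dense interior regime where the score is centred on zero.

**Reference definition.** Every movie in a benchmark cell — the ground-truth
movie included — is processed through the *identical* pipeline, including the
cell's correction variant. Corrected data are compared against the
identically corrected ground-truth-only movie; uncorrected data against the
raw ground-truth analysis. This isolates what the background and its
correction do to a reconstruction. The alternative (always comparing against
the raw ground-truth analysis) mixes in estimator noise: the one-to-two-count
residual of any finite-gate background estimate perturbs
overlapping-emitter fits by a few nanometres, an analysis artifact unrelated
to background removal. Under the symmetric definition, shift equivariance
makes corrected constant-background movies agree with their reference almost
exactly — the near-perfect restoration scores are a property of the method,
not of a lenient metric.

## Validation design and problem sizes

The acceptance analysis (`scripts/acceptance.R`) keeps the full 10,000-frame
acquisitions and the standard 200-frame gate — the ratio of gate to decay
timescale is part of the physics being validated, so it is not scaled — and
quarters the *field* instead (90 x 90 px at 100 nm pixels), with per-area
event densities preserved (star 17.2, array 0.95, lines 4.975 events per
frame in the quarter field, matching 68.8/3.8/19.9 in the full field). The
reported statistics are all intensive (percentages, correlations, per-event
distances), hence insensitive to field area; the whole grid (three
bright-gradient cells with corrected and uncorrected arms plus the twelve
decaying-background cells) completes on one desktop core in about ten
minutes. The test suite uses the same field with 100-10,000 frame stacks:
short stacks for temporally constant backgrounds (exactly removed at any
length by shift equivariance) and full-length stacks wherever a decaying
background is involved.

Other numerical choices: natural cubic interpolation of group statistics
anchored at group-centre frames and clamped beyond the first/last centre
(symmetric error at both stack ends); the final partial group uses the frames
it has (discarding them would bias the tail of decaying backgrounds);
monotone (Hyman-filtered) cubic for the decay profile so keyframe
monotonicity is preserved; float precision throughout the correction, with
rounding only at 16-bit TIFF export.

## Downstream quantification

Two biological quantifications operate on corrected, rendered images and are
validated purely on synthetic fixtures:

* **Ring (vesicle) detection.** Annulus-template matching over diameters
  50-250 nm: contrast = mean intensity on a one-pixel-wide ring minus mean
  intensity in the enclosed disk; candidates are local maxima of the
  best-template contrast above a threshold (default five standard deviations
  of the contrast map), pruned so no two accepted centres lie within one
  diameter, with much weaker side-lobe maxima within 1.5 diameters of an
  accepted ring discarded as template ghosts. The reported diameter is
  peak-to-peak (the template with maximal contrast). Automated matching
  replaces manual ring counting so the quantification is testable; a
  click-list CSV can be ingested instead for a manual workflow.
  `diameterStats()` adds the sample mean/SD and a least-squares Gaussian fit
  to the binned histogram whose centre estimates the mode — for right-skewed
  vesicle diameter distributions the mode falls below the mean.
* **Membrane-marker coverage.** Marker pixels above 75% of the image maximum
  (the literal fixed-fraction reading of the thresholding rule; an iterative
  intermeans auto-threshold is available behind a flag), intersected with a
  cell mask from a membrane stain (supplied, or an Otsu mask via EBImage),
  give coverage as a percentage of the mask area.

## Known limitations

* The uncorrected-data degradation magnitude depends on the absolute
  background intensity and the dye brightness distribution, neither of which
  is pinned by published parameters; the package's defaults reproduce the
  direction and the corrected-side restoration quantitatively, but
  uncorrected detection percentages should be read qualitatively.
* Cross-correlation drift estimation degenerates on structures that are
  translation-invariant along one axis (long straight lines); with the
  symmetric reference this cancels in comparisons, but absolute drift curves
  for such patterns are not meaningful.
* CBC retains its documented sparse-regime and edge biases.
* The correction assumes the background varies slowly relative to the gate;
  autofluorescence that flickers frame-to-frame violates the model and is out
  of scope of the simulator.
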