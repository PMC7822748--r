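Package: stormDefog
Title: Temporal Median Background Correction for Single-Molecule
    Localization Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Removes temporally stable background (such as cellular
    autofluorescence) from STORM/SMLM movie stacks using grouped temporal
    median or mean projections with cubic temporal interpolation, the
    moving-median filter in particular. Includes a blinking-fluorophore
    simulator with structured backgrounds, a wavelet-detection plus
    integrated-Gaussian maximum-likelihood localization pipeline with
    reblink merging, cross-correlation drift correction and average
    shifted histogram rendering, coordinate- and image-based restoration
    metrics (percent events, coordinate-based colocalization, nearest
    neighbor distance, Mander's overlap, Pearson correlation), and
    downstream quantification of nanoscale ring structures and membrane
    marker coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, tiff, yaml, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), EBImage
Config/testthat/edition: 3
biocViews: Software, Preprocessing, SingleCell, Visualization
RoxygenNote: 7.3.3
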