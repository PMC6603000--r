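Package: autostager
Title: Automated Staging of Autophagy, Mitophagy and Lysosomes from
    Dual-Channel Reporter Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image-analysis pipeline for high-content confocal screening of
    autophagy with tandem pH-sensor (pH-quenchable green / pH-stable red)
    reporters. Segments vesicles from dual-channel 3D z-stacks with
    difference-of-Gaussians, top-hat, Laplacian-of-Gaussian and Fourier
    band-pass filters, detects hollow autophagosomes by Euler-number topology
    and circle Hough transforms, and stages every vesicle as phagophore,
    autophagosome, early autolysosome or late autolysosome through a
    progressive-exclusion decision tree. Companion workflows segment the
    mitochondrial network and mitophagy events from matrix-targeted reporter
    stacks and size lysotracker-stained lysosomes. Includes Richardson-Lucy
    deconvolution with a parametric point-spread-function model, flatfield
    correction, per-field summary statistics (autophagic-vacuole counts,
    autophagy rate-constant, mitophagy volumes and frequencies), and a
    synthetic-field simulator with voxel-level ground truth for validating
    the whole pipeline without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
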