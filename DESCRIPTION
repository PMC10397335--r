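Package: pivalign
Title: Validating Particle Image Velocimetry Against Self-Propelled
    Particle Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates collectively moving self-propelled particles
    (Vicsek model) in a periodic box, renders them into synthetic 8-bit
    grayscale image sequences of oriented ovals, computes particle image
    velocimetry (PIV) displacement fields from those images by normalized
    cross-correlation over interrogation grids, and quantifies how
    faithfully the PIV field captures the underlying per-agent motion via
    an alignment score, local order parameters, and characteristic grid
    and radius scales.  Includes end-to-end experiment drivers for
    time-series, grid/radius and noise/radius landscapes, sampling-rate
    studies, and the order-disorder transition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
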