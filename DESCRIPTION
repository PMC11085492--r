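Package: veinclear
Title: Recovery and Enhancement of Degraded Vessel Transmission Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Restores and enhances degraded near-infrared finger-vein
    transmission images with a three-stage pipeline: bounded exponential
    gray-level quantization, local contrast recovery by inverting a
    tissue-scattering model (with a pixel-mutation filter and regional
    incident-light estimation), and global normalization by frequency-domain
    homomorphic filtering. Includes blockwise structural-similarity and
    contrast-improvement metrics, score-based FAR/FRR/EER evaluation, and a
    seeded synthetic vessel-phantom generator built on the same forward
    scattering model, so the whole pipeline is testable without external
    image datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
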