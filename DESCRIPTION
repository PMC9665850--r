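Package: netquant
Title: Automated Quantification of Neutrophil Extracellular Traps in
    Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments nuclei and neutrophil extracellular traps (NETs) from
    two-channel fluorescence micrographs (DNA stain plus antibody marker),
    scores per-image quality, classifies objects by nuclear area and
    normalized staining intensity, and computes the percentage of NETs per
    field of view under both a manual global-threshold regime and a fully
    automatic Bernsen local-threshold regime. Also provides the Manders
    channel-overlap coefficient, color-coded classification overlays, and a
    synthetic two-channel micrograph generator with ground truth so the
    whole pipeline is testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
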