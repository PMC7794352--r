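Package: srin
Title: Spatial RNA Integrity Scoring from Sequential Probe Hybridization Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes per-pixel spatial RNA integrity number (sRIN) maps from
    sequential fluorescence probe scans of 18S rRNA footprints on capture
    slides. A background autofluorescence scan (P0) and four probe scans
    (P1-P4) taken at increasing distance from the capture site are combined
    by quantile background thresholding and pixel-wise normalization into a
    0-10 integrity score per pixel, with masking of no-signal pixels and a
    chi-square diagnostic for inter-round misalignment. Includes a synthetic
    tissue-footprint simulator with an exponential fragment-length
    degradation model for end-to-end validation, summary statistics
    (RIN-sRIN correlation, hybridization efficiency, positive-pixel
    fractions, exon/intergenic read ratio), heat-map rendering, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    png,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
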