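Package: cytophase
Title: Quantification Pipeline for the Two-Phase (Cytosol/Cytomatrix) Model of the Cytoplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the two-phase model of the cytoplasm, in
    which a detergent-sensitive viscous fluid (cytosol) coexists with a
    detergent- and salt-resistant elastic solid (cytomatrix, CMX). The
    package implements the Hofmeister ionic-replacement calculation used to
    design isotonic fractionation buffers; a high-content-screening image
    analysis pipeline for nucleolar hypertrophy (watershed nuclei
    segmentation, best-focus plane selection, top-hat plus H-maxima spot
    detection, per-nucleus and per-well morphometry); fractionation and
    radiolabel-incorporation statistics (fraction percentages, percent
    change, abundance ratios, one-way ANOVA, Welch t-test); and a
    differential-expression filter with hypergeometric over-representation
    analysis and RNA-seq/Ribo-seq concordance. Ground-truthed synthetic
    generators for microscopy fields, assay tables and DEG universes make
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    withr,
    fgsea
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
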