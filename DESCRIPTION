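Package: cpcquant
Title: Whole-Slide Immunohistochemistry Quantification of Cardiac
    Progenitor Cell Markers
Version: 0.1.0
Authors@R:
    person("cpcquant", "maintainers", email = "cpcquant@example.org",
           role = c("aut", "cre"))
Description: Quantifies chromogenic immunohistochemistry (AEC chromogen,
    hematoxylin counterstain) on whole-slide brightfield images of
    myocardial biopsies: optical-density colour deconvolution, tissue
    masking with edge exclusion, positive-signal segmentation with
    single/concatenated classification, and per-section relative
    number/area metrics. Includes serial-section co-expression counting
    (rigid registration, representative-field selection, mutual
    nearest-neighbour matching), a logit-scale one-way ANOVA with
    Tukey-Kramer post-hoc comparisons for cohort analysis, and a
    seeded synthetic-slide generator with exact ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
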