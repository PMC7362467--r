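Package: lumiherb
Title: Delayed Luminescence and Chromatographic Fingerprint Chemometrics
    for Herbal Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrated quality assessment of medicinal herb batches from
    delayed-luminescence (DL) photon-count decay curves and HPLC
    chromatographic fingerprints. Fits the hyperbolic DL decay law by
    Poisson-deviance minimisation and derives decay-time summaries;
    builds common-peak matrices, relative retention times and relative
    peak areas against a reference peak, cosine similarity indices and
    reference-similarity-index (RSI) grouping; provides PCA, OPLS-DA
    with cross-validated R2/Q2, Ward hierarchical clustering, and a
    thresholded Spearman correlation network linking DL properties to
    chemical constituents; computes cathartic-bioassay statistics
    (diarrhea incidence, charcoal propelling ratio, one-way ANOVA with
    Levene-gated LSD or Tamhane T2 post hoc, chi-square and Fisher exact
    tests); and ships a deterministic synthetic-cohort generator so the
    full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
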