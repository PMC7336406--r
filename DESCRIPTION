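Package: orthodiv
Title: Orthogroup Annotation Transfer, Protein Divergence and
    Species-Composition Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of orthogroups across a small set of
    related species: transfer of reference-species transcript annotations
    to orthogroups with mix/conflict resolution, cross-species
    differential-expression consistency calling, per-orthogroup protein
    divergence from maximum-likelihood pairwise amino-acid distances under
    the Jones-Taylor-Thornton (JTT) model, a resampling test of orthogroup
    species composition by annotation, a chi-square goodness-of-fit test
    of signal-peptide enrichment, and a synthetic-data generator that
    emulates all required input formats so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
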