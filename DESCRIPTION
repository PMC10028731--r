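Package: sigmascan
Title: Sigma-Factor Binding-Site Discovery from ChIP-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from bacterial ChIP-seq per-base coverage to a
    sigma-factor binding motif and genome-wide binding-site predictions.
    Implements median-per-base coverage normalization, dual-threshold peak
    calling against input and mock-IP controls, triangularity screening of
    peak shape, summit-centered site-window extraction, ZOOPS
    expectation-maximization motif discovery, per-position information
    content (R_seq) with background masking of uninformative columns,
    log-odds scanning with exact dynamic-programming p-values and
    Benjamini-Hochberg q-values, strand-aware promoter extraction, and a
    synthetic ChIP coverage simulator with ground-truth manifests for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
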