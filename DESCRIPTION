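Package: barcodeAudit
Title: Audit and Reliability Grading of DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit COI-5P DNA barcode reference libraries the way
    curators of regional barcoding campaigns do: sequence vetting against the
    invertebrate mitochondrial genetic code (stop codons, frameshifts,
    reading-frame-preserving indels in Folmer coordinates), Kimura
    2-parameter distance summaries at species, genus and family rank,
    BIN-style MOTU delimitation by single-linkage clustering at a divergence
    threshold, concordance review of clusters against morphological
    identifications with synonym resolution, an A-E per-species reliability
    grading, neighbor-joining phenograms with nonparametric bootstrap, and a
    calibrated synthetic-library generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
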