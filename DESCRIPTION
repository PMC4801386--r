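Package: sialoquant
Title: Tissue-Enrichment Analysis of Mosquito Salivary-Gland Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and classifies salivary-gland (SG) enriched transcripts
    from four-library mosquito RNA-seq designs (female/male salivary gland and
    female/male whole body). Implements quality trimming, blastn-style
    seed-and-extend read-to-CDS assignment with a 95 percent identity filter,
    RPKM/TPM/Expression-Index quantification, pseudocounted cross-library
    ratios, per-CDS chi-square enrichment testing with Bonferroni and
    Benjamini-Hochberg correction, the tenfold-salivary/fivefold-sex
    classification scheme, an extreme tissue-specificity screen, six-frame ORF
    bookkeeping, and qPCR 2^-ddCt concordance analysis. A seeded synthetic-data
    generator plants known enrichment structure so the whole pipeline can be
    validated end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    tibble,
    dplyr,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    readr
Config/testthat/edition: 3
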