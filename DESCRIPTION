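Package: gxscreen
Title: Genome Contamination Screening with Hashed k-mer Cross-Species Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens genome assemblies for cross-species contamination at desk
    scale. Reference genomes are indexed with locality-sensitive 38-bit hashed
    k-mers ("h-mers": 56-bp windows with codon-wobble positions dropped and a
    one-bit purine/pyrimidine alphabet, canonicalized over strands), queries are
    aligned with a two-pass seed-and-extend aligner, and a rule-based classifier
    assigns sequences to primary, contaminant or inconclusive categories and
    emits one of six cleaning actions (EXCLUDE, TRIM, FIX, INFO, REVIEW,
    REVIEW_RARE) together with a cleaned FASTA. Includes a synthetic-genome
    simulator and sensitivity/specificity evaluation utilities so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
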