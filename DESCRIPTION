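Package: viromedeck
Title: Decontamination, Standardisation and Discovery Workflows for Virome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of shotgun virome sequencing
    experiments that include negative controls: abundance thresholding and
    negative-control subtraction of taxon read-count tables, per-kilobase
    abundance standardisation, sample-based taxon accumulation (rarefaction)
    curves, reciprocal-best-hit confirmation of candidate viral contigs,
    reference-guided consensus calling from per-position pileups with a
    minimum-depth rule, affine-gap global pairwise alignment and identity
    matrices, six-frame ORF scanning and coding-sequence completeness,
    ICTV-style pairwise-identity species demarcation, and in-silico PCR with
    IUPAC-degenerate primers. A synthetic-community generator with planted
    ground truth (cross-sample contamination, substitutions, false-positive
    hits) makes every stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
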