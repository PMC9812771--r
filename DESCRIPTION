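Package: tropicr
Title: Somatic Tandem Repeat Expansion Discovery from Tumour-Normal Short-Read Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recurrent somatic tandem repeat expansions in tumour-normal
    whole-genome sequencing cohorts from anchored in-repeat read (IRR) evidence.
    Provides repeat-motif canonicalization and in-repeat-read classification, anchored
    IRR event collection and clustering from coordinate-sorted alignments, global and
    local (copy-number aware) read-depth normalization, a case-control prioritization
    cascade (one-sided rank-sum testing with Benjamini-Hochberg FDR, anchored IRR
    quotient calling, and a local read-depth refilter that separates true expansions
    from chromosomal amplification), population expansion-frequency estimation across
    read lengths, locus annotation statistics (feature distances, motif enrichment,
    cohort gene-mutation association), and a seed-deterministic diploid tumour-normal
    read simulator with truth tables for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
LinkingTo: Rcpp
Config/testthat/edition: 3
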