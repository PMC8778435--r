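Package: prophagr
Title: Prophage Discovery, Diversity and Activity Analysis for Bacterial Genome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the prophage complement of a bacterial
    species from genome assemblies: pangenome ortholog clustering with Heap's-law
    openness fitting, hallmark-gene prophage discovery with reference-based
    boundary delineation and att-site prediction at tRNA integration loci,
    fragmented nucleotide-identity clade clustering, CRISPR spacer-to-protospacer
    matching under mismatch and bit-score thresholds with PAM annotation,
    detection of diversity-generating retroelements (template/variable repeat
    pairs anchored on a reverse transcriptase) and site-specific invertase
    shufflons, and prophage-activity evidence from read-depth ratios and
    in-silico excision/circularisation PCR. Includes a deterministic synthetic
    genome-cohort generator with a machine-readable truth table so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
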