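Package: strseq
Title: Microsatellite Genotyping by Sequencing for Canid Panels
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls short tandem repeat (STR) genotypes from multiplexed
    amplicon sequencing reads using explicit read-ratio and stutter rules,
    decomposes alleles into forward-flank, repeat-array and reverse-flank
    regions, encodes sequence-level mutations into homoplasy-aware numeric
    allele codes, matches duplicate multilocus genotypes, quantifies
    paired-scoring error rates, and compares allelic diversity between
    length-only and mutation-aware datasets. Includes a seeded amplicon
    read simulator with stutter ladders, sequencing error and allelic
    dropout so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
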