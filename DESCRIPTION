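Package: colidiv
Title: Population Diversity Analysis of Commensal Escherichia coli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing the population structure of commensal
    bacterial isolates. Implements ortholog family construction under an
    identity/coverage homology criterion, core- and pan-genome accumulation
    curves with a Heaps-style openness index, a genetic-boundary statistic
    (the fraction of shared one-to-one homologous genes with identical
    nucleotide sequences), concatenated core-gene neighbor-joining
    phylogenies with bootstrap supports, in-silico macro-restriction (PFGE)
    digestion and band-pattern genotyping (I-CeuI and CTAG-recognizing
    enzymes), and cohort-level genotype-diversity statistics with exact and
    approximate Wilcoxon rank-sum tests. A seeded synthetic-population
    generator emits lineage-structured genomes and host cohorts with a truth
    set for parameter-recovery testing, and a packaged per-subject genotype
    table supports the cohort statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
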