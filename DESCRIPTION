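Package: vatkit
Title: Simulation and Analysis of Tandem-Repeat NLR Resistance-Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying clusters of NLR (nucleotide-binding-site
    leucine-rich-repeat) resistance-gene homologs whose LRR2 domain carries a
    variable number of near-identical 65-amino-acid (195-nt) repeat units.
    Includes a ground-truthed cluster-evolution simulator (duplication, unequal
    crossover gain/loss of repeat units, transposable-element insertion and
    premature-stop pseudogenisation, retro-copy to the reverse strand),
    seed-and-extend homology scanning and gene-model classification, repeat-unit
    annotation and virtual-CDS (repeat-excised) construction, in-silico PCR with
    decoding of amplicon band patterns into per-accession homolog counts and
    repeat-number digit strings, a per-site nonsynonymous-probability statistic
    with kernel smoothing and permutation confidence bands, and distance-based
    phylogenetics (Tamura-Nei 1993 distances, neighbor joining with bootstrap,
    and a simplified two-segment incongruence breakpoint scan).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
SystemRequirements: MAFFT (for progressive_align())
Config/testthat/edition: 3
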