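Package: panforge
Title: Pan-Genome Construction, Selection and Gene-Flow Analysis for Bacterial Genome Sets
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds orthologous gene families from pairwise protein similarity
    tables by Markov clustering, partitions them into core, accessory and
    strain-specific sets, fits Heaps' law to pan-genome accumulation curves,
    reconstructs single-copy supermatrix and gene-content (presence/absence)
    phylogenies, estimates dN/dS per family by Nei-Gojobori counting and by
    maximum likelihood under a single-ratio codon model, infers gene-family
    expansion and contraction along the species tree under a birth-death
    size-change model, detects horizontally transferred genes from the
    taxonomic structure of best-hit profiles, and profiles the synteny of the
    metal-reduction (mtr-omc) gene cluster across genomes. Ships a fully
    seeded synthetic-data generator with known orthology, gene-content
    history, selection regime and transfer events so that every stage can be
    benchmarked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    ape,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
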