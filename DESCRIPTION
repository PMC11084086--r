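Package: cubtools
Title: Synonymous Codon Usage Bias Analysis for Organellar Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for analysing synonymous codon usage
    bias (CUB) in sets of protein-coding genes organised as strains x genes,
    aimed at AT-rich organellar (mitochondrial) genomes. Reads coding
    sequences from FASTA or GenBank flat files, computes nucleotide and
    codon-position composition (GC1/GC2/GC3, GC3s, synonymous third-position
    base frequencies), the classical usage indices (RSCU, Wright's effective
    number of codons, CAI, CBI, FOP, GRAVY, aromaticity), the three
    mutation-versus-selection diagnostics (neutrality plot, ENC-GC3s plot
    with expected curve and ENC ratio, PR2-bias plot), correspondence
    analysis of RSCU, optimal-codon determination via the delta-RSCU rule,
    and RSCU-based hierarchical clustering of strains with Newick export.
    Includes a synthetic codon-biased CDS generator so every stage is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
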