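Package: linctools
Title: Comparative Characterization of Long Intergenic Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for comparative analysis of long
    intergenic noncoding RNAs (lincRNAs) across species. Computes
    per-transcript sequence properties (GC content by compartment, longest
    open reading frames, exonic structure), thermodynamic structural
    stability statistics against dinucleotide-preserving shuffled null
    models (minimum free energy, base-pair probabilities and folding
    strength from a built-in partition-function engine, Z-scores and
    shuffle ratios), structured-transcript selection by folding-strength
    quantile, cross-species conservation and within-species paralogy via
    seed-and-extend local alignment with Karlin-Altschul e-values and
    Markov clustering, transposable-element overlap by genomic
    compartment, and genomic-context analyses (closest genes, Gene
    Ontology enrichment, expression-distance profiles, chromosomal
    density). Includes a fully seeded synthetic-data generator that plants
    known structure, homology, repeat and expression signal so the whole
    pipeline is testable end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    rtracklayer,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
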