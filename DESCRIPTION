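Package: rhizotrace
Title: Source Tracing and Succession Analysis for Serially Propagated
    Rhizosphere Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing serial-propagation (selection-cycle)
    rhizosphere microbiome experiments in which a soil inoculum and
    seed-borne bacteria coalesce into a stable community. Provides a
    synthetic-community simulator with known ground truth (serial
    transfer with replicator dynamics and multinomial sequencing noise),
    cumulative sum scaling (CSS) normalization, alpha and beta diversity
    metrics, exact-sequence source tracing with contribution accounting
    and ASV emergence curves, a negative-binomial Wald differential
    abundance test, ternary dominance classification of functional
    annotations, MAG quality tiers with TPM-based community assignment
    and reaction-set pathway completeness, and the supporting
    non-parametric statistics (Kruskal-Wallis with rank LSD letters,
    Wilcoxon, ANOSIM, PERMANOVA) plus co-culture growth normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    ape,
    vegan,
    yaml,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    picante,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
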