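Package: mirdrop
Title: Analysis of Pooled Lentiviral miRNA Dropout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deconvolution of pooled lentiviral miRNA precursor screens read
    out by two-channel microarrays: per-channel median normalization,
    duplicate summarization with a coefficient-of-variation reproducibility
    filter, and fold-change classification of dropout and retained miRNAs
    under drug selection. Includes a generative simulator of the pooled
    screen (Poisson infection, exponential clonal selection, log-normal
    array noise) for parameter-recovery validation, k-of-n consensus over
    target-prediction gene lists, canonical miRNA seed-site scanning of
    3'-UTR and reporter sequences, and downstream validation statistics
    (2^-ddCt relative quantification, dual-luciferase normalization,
    viability fold changes, and an exact Wilcoxon signed-rank test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
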