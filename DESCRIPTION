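Package: exodep
Title: Differential Spectral-Count Proteomics with a Conjunction Significance Gate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free differential proteomics for spectral-count data from
    two-group designs, as used to compare retinal-pigment-epithelium exosome
    cargo between myopic and non-myopic eyes. Implements Scaffold-style
    peptide- and protein-level evidence filtering, between-sample
    normalization of spectral counts (N-SC), a SAM-like group-separation
    weight statistic, one-tailed Welch testing, empirical fold-change
    threshold calibration from control replicate ln-ln plots, a
    three-criterion conjunction significance gate, presence/absence Venn
    partitioning, hypergeometric over-representation analysis against GMT
    gene sets, and volcano/PCA/heatmap reporting tables. A negative-binomial
    synthetic-study generator with known ground truth allows the whole
    pipeline to be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
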