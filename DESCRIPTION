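Package: multindel
Title: Multi-InDel Ancestry-Informative Marker Discovery and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and validating multi-InDel ancestry
    informative markers. Provides a hierarchical Balding-Nichols simulator of
    phased insertion/deletion cohorts, per-site Weir-Cockerham FST estimation
    with a two-tier threshold screen, greedy clustering of tightly spaced
    InDels into multi-allelic haplotype markers with capillary-electrophoresis
    amplicon-size encoding, haplotype-frequency estimation by counting, a
    naive-Bayes population-assignment classifier with blind-trial evaluation,
    a no-admixture Gibbs sampler for model-based clustering with Evanno
    delta-K model choice, and genotype principal component analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
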