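Package: metabolodiv
Title: Ecology-Style Diversity, Chemometrics, Differential Marker and
    Pathway Analysis of Dual-Polarity LC-MS Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage analysis pipeline for untargeted metabolomics
    feature tables acquired in both electrospray ionization (ESI) modes.
    Treats each m/z-retention time feature as a "species" and profiles the
    metabolome with community-ecology tools (species accumulation curves,
    Chao1 and jackknife richness estimators, Shannon diversity, Pielou
    evenness, rank-abundance null fits); discovers sample structure with
    quantile/log normalization, PCA, Ward/Pearson hierarchical clustering
    and decision-tree factor ranking; calls differential chemical markers
    by two-sided fold change with per-mode calling followed by cross-mode
    set merging; and annotates differential m/z presumptively against a
    compound database via adduct arithmetic within a ppm tolerance,
    feeding hypergeometric and permutation pathway over-representation.
    Includes a ground-truthed synthetic data generator for dual-mode
    feature communities with planted fold-change effects and
    compound-derived m/z values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
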