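Package: biofilmnet
Title: Cross-Domain Co-Occurrence Networks and Stability of Stream Biofilm Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cross-domain (bacteria, eukaryotic phototroph, fungus)
    co-occurrence networks from paired 16S/18S amplicon count tables using an
    ensemble of SparCC basis correlations, Spearman rank correlations and
    Meinshausen-Buhlmann neighborhood selection with StARS regularisation, and
    characterises the resulting networks: Louvain communities, topology metrics,
    keystone taxa by joint degree/betweenness rank, and fragmentation under
    iterative keystone removal. Includes distance-based redundancy analysis
    (db-RDA) with permutation-based forward selection to quantify the variance
    in bacterial community composition explained by keystone taxa versus
    environmental gradients, family-level two-way ANOVA enrichment tests, and a
    synthetic-data generator that plants a known sparse interaction network with
    hub taxa under a logistic-normal-multinomial sampling model so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
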