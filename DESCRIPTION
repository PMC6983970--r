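Package: prognet
Title: Master Prognosis Genes and Expression Subtypes via Causal Regulatory Networks
Version: 0.1.0
Authors@R:
    person("prognet", "developers", email = "prognet@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying master prognosis-impacting genes in
    tumor expression cohorts and deriving prognosis-relevant expression
    subtypes. Genes are screened genome-wide with univariate Cox
    proportional-hazards models, a causal regulatory network among the
    prognosis-relevant genes is estimated with the PC algorithm on a
    biweight-midcorrelation matrix, and hub ("master") genes are scored by
    summarized degree (out-degree minus in-degree). Samples are clustered
    into subtypes by consensus clustering (PAM over subsampled repeats),
    the prognostic value of the subtypes is calibrated against a
    random-gene-set null, genes are ranked by random-forest permutation
    importance, top genes are tested for pathway enrichment
    (hypergeometric), mutations are related to subtypes and expression
    (Fisher exact, two-sample tests), and an elastic-net logistic predictor
    transfers subtype labels to external cohorts. A synthetic-data module
    with planted causal structure, subtypes, survival effects and mutations
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    cluster,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
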