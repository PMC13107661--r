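Package: morbnet
Title: Multimorbidity Pattern Discovery from Chronic Disease Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates conditional-independence networks of chronic diseases
    from binary diagnosis indicators by nodewise L1-penalized logistic
    regression (the binary mixed graphical model), detects multimorbidity
    patterns as modularity-selected hard communities, scores diseases by
    strength centrality and Bayesian-network in-degree to assign each
    multimorbid individual a unique pattern per follow-up wave, identifies
    gatekeeper diseases by weighted betweenness centrality together with
    their strongest comorbid dyads, and quantifies impacts on mortality
    (time-dependent Cox models), unplanned hospitalization (overdispersed
    counts) and length of stay. Includes a synthetic closed-cohort simulator
    with block-structured Ising disease dependence, monotone disease
    accumulation across waves, and survival, hospitalization and
    length-of-stay outcomes, so the full pipeline is testable without
    access to administrative health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    survival,
    MASS,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
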