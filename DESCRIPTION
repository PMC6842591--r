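Package: bcrphylo
Title: Repertoire-Wide Phylogenetic Models of B-Cell Receptor Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood phylogenetic analysis of B-cell receptor (BCR)
    repertoires under codon substitution models tailored to somatic hypermutation
    (SHM). Implements the germline-rooted, nonreversible HLP19 model with
    hot-/cold-spot motif rate modifiers (WRC, GYW, WA, TW, SYC, GRS), separate
    dN/dS ratios for framework and complementarity-determining regions, and the
    GY94 and HLP17 baselines. Likelihoods of whole repertoires are maximized
    jointly across clonal lineage trees that share substitution parameters;
    profile-likelihood confidence intervals, likelihood-ratio tests and AIC model
    comparison are provided, together with maximum-parsimony topology inference,
    a fully context-dependent SHM sequence simulator (HLP19 and 5-mer mutability
    table variants) and a synthetic-repertoire generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    phytools,
    Biostrings,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    yaml
Config/testthat/edition: 3
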