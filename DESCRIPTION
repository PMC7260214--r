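Package: methkinetics
Title: Inference of DNA Methylation Turnover Rates from Bisulfite Time Courses
Version: 0.1.0
Authors@R:
    person("methkinetics", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers per-CpG de novo methylation and demethylation rates from
    time-resolved bisulfite sequencing count data collected after induced loss
    of the de novo methyltransferases DNMT3a/b. Provides a two-rate dynamical
    model with exponential dampening of the methylation rate, corrections for
    incomplete allele excision and bisulfite conversion error, binomial and
    beta-binomial observation models, brute-force Bayesian inference over a
    multiplicative rate grid with marginal credible intervals and a border-mass
    identifiability rule, the full identifiability landscape of the assay
    design, a steady-state-based estimator of TET-driven demethylation
    activity, and a synthetic-data generator emulating the assay for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
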