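Package: SynFBA
Title: De Novo Syntrophy in Random Viable Metabolisms via Flux Balance Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools to study the spontaneous (de novo) emergence of syntrophy
    between metabolisms that share no evolutionary history. Provides
    constraint-based metabolic model containers, flux balance analysis with a
    built-in bounded-variable simplex solver, a viability-constrained Markov
    chain Monte Carlo reaction-swap sampler of random viable metabolisms,
    pairwise syntrophy detection through pooled and explicit metabolite
    exchange models, minimal-exchange computation by branch and bound,
    syntrophic-potential statistics with a no-exchange null model, and
    core-periphery analysis of the carbon-source syntrophy network. A
    synthetic reaction-universe generator makes the entire pipeline testable
    without external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    xml2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
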