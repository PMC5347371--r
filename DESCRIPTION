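Package: pleiograph
Title: Joint Bayesian Analysis of GWAS Summary Statistics with a Hidden
    Markov Random Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates genome-wide association study (GWAS) summary
    statistics (p-values) for multiple phenotypes under a Bayesian hidden
    Markov random field model. Latent per-SNP association indicators are
    coupled across phenotypes through a sparse auto-logistic Markov random
    field whose graph is learned by reversible-jump MCMC, yielding a
    phenotype-pleiotropy graph, per-phenotype and per-pair local false
    discovery rates, and FDR-controlled association calls via the direct
    posterior probability approach.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
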