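Package: enrollscape
Title: Small-Area Bayesian Mapping and Modelling of Disease-Management-Program Unenrollment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial-epidemiological toolkit for quantifying and explaining
    small-area disparities in unenrollment from chronic-disease management
    programs. Provides contiguity graphs and intrinsic conditional
    autoregressive (ICAR) structure matrices, a rank-based multi-domain
    area deprivation index, Besag-York-Mollie (BYM) Poisson disease mapping
    with Matern Gaussian-process surface interpolation, the Kulldorff
    purely spatial Poisson scan statistic with Monte-Carlo inference,
    individual-level Bayesian spatial logistic regression (iid, Besag and
    BYM area effects) with variance-inflation screening and DIC model
    comparison, a Bayesian spatially varying coefficient model with
    exceedance probabilities, a synthetic-region generator with known
    ground truth, and a seeded, resumable analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
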