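Package: jointabund
Title: Joint Hierarchical Modelling of Structured and Semi-Structured Bird Count Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Hierarchical Bayesian state-space models for estimating grid-cell
    relative abundance and log-linear trends of bird populations from structured
    route-count surveys (North American Breeding Bird Survey style) alone, or
    jointly with semi-structured community-science checklists (eBird style).
    Counts follow zero-inflated Poisson observation models with route-by-observer
    and observer random effects, an effective-survey-area offset for route counts,
    and effort covariates with a free scaling intercept for checklists; cell-level
    intercepts and slopes are pooled within ecoregions. Includes a forward
    simulator with the exact generative structure of the model, checklist quality
    filtering and spatiotemporal subsampling on a hexagonal grid, a Gibbs sampler
    written in C++, Gelman-Rubin convergence diagnostics, posterior predictive
    zero-fraction checks, and credible-interval-based coefficient-of-variation
    comparisons of precision between models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    withr
Config/testthat/edition: 3
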