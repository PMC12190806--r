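Package: effscape
Title: Pollinator Effectiveness Landscapes and Interaction Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for quantifying how pollinator effectiveness
    (visit quantity times per-visit quality) changes the measured
    generalisation of a plant's pollination system. Implements Hurlbert's
    probability of interspecific encounter with bootstrap confidence
    intervals, Bray-Curtis beta-diversity tests (permutational multivariate
    ANOVA, principal-coordinates ordination with functional-group score
    projection), Jacobs' D and Ivlev's E electivity analysis of two-morph
    preference trials, construction of the quantity-by-quality effectiveness
    landscape with spatial-pattern diagnostics (Clark-Evans R with Donnelly
    edge correction, Hopkins-Skellam A, Monte Carlo significance) and
    majority-rule cluster-number estimation, plus a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
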