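Package: domcert
Title: Dominance Rank, Status Certainty, and Health in Primate Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers dominance rank and dominance certainty from networks of
    dyadic agonistic interactions using a percolation-and-conductance style
    approach: exhaustive enumeration of directed dominance pathways,
    transitivity-weighted imputation of indirect wins, Beta-distribution
    dyadic dominance probabilities, and a simulated-annealing lowest-cost
    linear ordering.  Relates the resulting status measures to health
    outcomes (pro-inflammatory biomarkers and diarrhea bouts) through
    AICc-based multimodel inference over negative-binomial and gamma mixed
    models with a group random intercept.  Ships a synthetic colony
    generator with retained ground truth so the whole pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmmTMB,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
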