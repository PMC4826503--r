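Package: isletcea
Title: Cost-Utility and Value-of-Information Analysis of Islet Cell
    Transplantation for Unstable Type 1 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-time Markov cohort model comparing allogeneic islet
    cell transplantation (up to four transplantations per patient) with
    intensive insulin therapy in adults with unstable type 1 diabetes and
    hypoglycemia unawareness, from a provincial healthcare payer perspective
    (2012 Canadian dollars). Provides a parameter registry with full
    distributional specifications, a calibrated synthetic background life
    table, a vectorized C++ cohort engine with half-cycle correction and
    discounting, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves and frontiers, net benefit probability maps,
    expected value of perfect information and nested two-level expected
    value of partial perfect information, and an 18-row scenario grid over
    discount rates, immunosuppression prices, life-expectancy assumptions,
    disutilities and cost multipliers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    ggplot2
Config/testthat/edition: 3
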