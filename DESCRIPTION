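Package: carescape
Title: Life History, Sexual Selection, and the Elaboration of Paternal Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation tools for a life-history model of male
    lifetime fitness in which males provide paternal egg care and may also
    carry a non-care mating trait preferred by females. Evaluates the
    cost/benefit fitness equations exactly under four mate-preference
    scenarios and two investment regimes (a fixed care-plus-trait budget, or
    free investment), runs parameter sweeps with scenario ranking and
    bisection-refined crossover detection, classifies the monotonicity of
    fitness in the investment traits, and validates the analytic lifetime
    fitness against a seeded individual-based Monte-Carlo simulation of male
    reproductive careers with binomial fertilization and truncated-geometric
    survival across reproductive episodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
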