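Package: pairfeedsim
Title: Monte Carlo Evaluation of Type I Error in Pair-Feeding Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pair-feeding (yoked-control) animal experiments under
    the null hypothesis of no treatment effect and quantifies the type I
    error rate of common analysis strategies. Supports group pair-feeding
    (pair-fed intake capped at the previous day's mean intake of the
    ad-libitum group) and individual pair-feeding (animals matched by
    baseline weight rank, intake capped at the partner's previous-day
    intake). Body weight follows a calorie-balance recursion around a fixed
    maintenance intake. Each simulated trial is analysed by ordinary least
    squares with and without adjustment for within-animal mean food intake,
    and, for the individual design, by linear mixed models with a pair
    random intercept. Empirical rejection rates are compared with the
    nominal alpha by chi-square goodness-of-fit tests, and the two designs'
    induced intake deficits are compared by a t-test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    patchwork,
    optparse
Config/testthat/edition: 3
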