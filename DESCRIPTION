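Package: ptrank
Title: Prospect Theory Parameters and Social Rank from Longitudinal Choice Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how dominance hierarchy relates to risky
    economic decision-making in group-living primates tested on automated
    gambling devices. Fits a seven-parameter Prospect Theory model (utility
    curvature in gains and losses, loss aversion, Prelec probability
    weighting, sigmoid choice steepness and side bias) to consecutive
    1500-trial windows of two-lottery choice data by maximum likelihood;
    tracks Elo-rating trajectories and conflict outcome predictability from
    displacement-event logs; filters outlying fits by the interquartile-range
    rule; and tests rank-risk relationships with linear mixed models
    containing quadratic hierarchy terms. A synthetic-cohort generator with
    known ground truth supports parameter-recovery and end-to-end validation
    without access to animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
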