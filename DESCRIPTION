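Package: cvdsynth
Title: Synthetic National Populations with Joint Cardiovascular Risk Factor Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates synthetic individual-level adult populations
    carrying the full joint distribution of cardiovascular disease (CVD) risk
    factors, by combining aggregated census cross-tabulations (with
    small-cell-suppression handling), conditional probability tables estimated
    from linked administrative records, and chained-equations imputation from a
    donor cohort (predictive mean matching for continuous variables, logistic
    draws for binary ones). Includes post-hoc mean-shift adjustment of
    continuous variables to external reference estimates, internal and external
    validation (including adjusted odds ratios and replicate-population
    variability), and a configurable ground-truth world generator for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    arrow,
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
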