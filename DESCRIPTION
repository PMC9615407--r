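Package: saerep
Title: Assessing Trial Representativeness from Serious Adverse Event Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the representativeness of randomised
    controlled trials by comparing observed serious adverse event (SAE)
    counts against counts expected under routine-care hospitalisation and
    death rates. Sex-stratified fractional-polynomial Poisson rate models
    are fitted to a routine-care cohort; trial age/sex structure is either
    observed (individual participant data) or reconstructed from registry
    summary statistics via moment-matched truncated normal distributions;
    expected counts follow by indirect standardization. Per-trial
    observed/expected ratios carry sampling-based 95% intervals, and
    condition-level ratios are pooled with a random-effects Poisson model
    using the expected count as an offset. Includes medication-derived
    multimorbidity counting, a multimorbidity-adjusted standardization,
    arm-level rate-ratio comparisons with random-effects meta-analysis,
    and a synthetic-data generator with planted trial-selection effects
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    metafor
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    ggplot2
Config/testthat/edition: 3
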