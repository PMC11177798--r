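Package: sctbias
Title: Selection-Bias Risk Testing for Controlled Clinical Trials via
    Simulated Comparator Trials and the I2 Point Estimate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests a single prospective controlled clinical therapy trial for
    selection-bias risk from its published baseline summaries alone. Two
    simulated comparator trials (SCTs) with ideal block-randomised allocation
    of uniformly sampled baseline values are generated, confirmed to pool with
    zero heterogeneity, and combined with the candidate trial's baseline
    mean/SD/n per arm in a fixed-effect inverse-variance meta-analysis of the
    mean difference; a non-zero I2 point estimate flags the trial as at risk
    of selection bias. Includes the summary-statistic conversions reviewers
    need in practice (median/range to mean/SD, standard error to SD), replay
    of published worked examples, and a simulation study estimating the
    sensitivity and specificity of the test under a controllable directional
    misallocation mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
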