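Package: faersignal
Title: Pharmacovigilance Signal Detection and Time-to-Onset Modelling for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for disproportionality analysis of
    FAERS-style individual case safety reports. Reads '$'-delimited quarterly
    ASCII tables, removes duplicate reports with the two-stage
    (case-version, six-field redundancy) rule, restricts to primary-suspect
    drugs, maps reactions to MedDRA preferred terms and aggregates them to a
    standardized query, and computes four disproportionality statistics
    (reporting odds ratio, proportional reporting ratio with Pearson
    chi-square, information component, and the gamma-Poisson shrinker's
    empirical Bayes geometric mean) with intervals, Bonferroni-corrected
    p-values, conventional signal criteria and a consensus flag.
    Time-to-onset is modelled with a Weibull distribution fitted by maximum
    likelihood and classified into early, random, or wear-out failure
    patterns. A synthetic report generator with planted reporting-rate
    ratios, Weibull onset times, demographic mixes and injected duplicates
    makes the whole pipeline testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vctrs,
    withr
Suggests:
    broom,
    fitdistrplus,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
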