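Package: fmtsuccession
Title: Ecological Succession Analysis for Longitudinal Fecal Microbiota
    Transplantation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks the fate of individual gut microbial species after fecal
    microbiota transplantation (FMT) in longitudinally sampled recipients.
    Species are assigned per recipient and timepoint to one of nine ecological
    categories crossing origin (recipient-derived, donor-derived, novel) with
    temporal status (stable, transient, lost), using a presence/absence state
    machine with a tolerated single absence and four sensitivity variants.
    Donor reference sets are derived by core-microbiota abundance thresholding.
    Category counts over time are modelled with negative-binomial generalized
    linear mixed models (log link, patient random intercept, spline or linear
    time, responder interactions) fitted by adaptive Gauss-Hermite quadrature,
    with Wald tests on coefficient groups. Abundance-level analyses relate
    baseline abundance to species fate and compute pre/post log-abundance
    differences with linear mixed models. A synthetic-study generator with
    multinomial read sampling provides ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    lme4,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    glmmTMB,
    optparse,
    withr
Config/testthat/edition: 3
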