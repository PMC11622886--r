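Package: fpemsub
Title: Subnational Family Planning Estimation with Service-Disruption Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian hierarchical estimation and projection of modern
    contraceptive prevalence, unmet need for modern methods, and demand
    satisfied with modern methods across a country-region-division
    hierarchy, in the style of the family planning estimation model
    (FPEM/FPET): logistic growth trends with AR(1) distortions on the
    logit scale, survey likelihoods with source-dependent variance
    inflation, and pooling of subnational parameters toward fixed
    country-level values. Includes derived target metrics for the FP2030
    (1.4 percentage-points/year) and SDG (75 percent demand satisfied by
    2030) benchmarks, a coverage-disruption scenario engine linking
    provision and utilization indices to prevalence projections, and a
    synthetic data generator emulating DHS/MICS-style survey inputs so
    the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
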