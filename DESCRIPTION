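Package: mhdid
Title: Event-Study Difference-in-Differences for Mobile Health App Adoption
    and Hospital Visits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quasi-experimental estimation of how mobile health and
    fitness app adoption changes hospital visits, measured from hourly
    geolocation epochs. Provides a synthetic-data generator with known
    ground-truth dynamic treatment effects (staggered adoption, a used versus
    installed-but-never-used adopter split, zero-inflated monthly hospital
    hours), construction of monthly hospital-visit durations from epoch streams
    under consecutive-epoch rules, estimation panels with event-time coding, a
    from-scratch high-dimensional fixed-effects least-squares engine with
    cluster-robust (CR1) inference, declarative builders for dynamic
    difference-in-differences, triple-difference (DDD) and moderation
    specifications, pre-trend assessment, and an end-to-end pipeline with a
    sensitivity battery over visit rules and adoption windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    arrow,
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
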