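Package: dpnflow
Title: Temporal Drug Co-Prescription Network Analysis of Dispensing Registries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds daily drug co-prescription networks (DPNs) over 24
    Anatomical Therapeutic Chemical (ATC) therapeutic classes from pharmacy
    dispensing records, weights edges with a Gaussian kernel on defined daily
    dose (DDD) ratios, tracks eigenvector centrality over time against the
    uniform 1/n baseline, summarises same-class, multi-class and total
    co-prescription as prescription-days, labels age and polypharmacy
    subgroups, and decomposes the weekly series with a two-stage singular
    spectrum analysis followed by Mann-Kendall trend tests. A configurable
    synthetic dispensing-registry simulator reproduces the statistical
    structure such analyses assume (weekday dispensing cycle, yearly
    seasonality, class trends, multimorbidity-driven co-prescription), so the
    whole pipeline can be exercised end to end without access to a
    proprietary registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
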