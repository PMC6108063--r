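Package: lviaes
Title: Livelihood Vulnerability Index Analysis at Agroecosystem Scale
Version: 0.1.0
Authors@R: person("LVI", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to compute the Livelihood Vulnerability Index (LVI) and its
    IPCC-framework variant (LVI-IPCC) from stratified household survey data
    aggregated to agroecosystem (AES) units. Covers the full chain from raw
    household records to per-unit indicator tables, min-max standardization,
    profile scores, exposure/sensitivity/adaptive-capacity contributing
    factors, composite indices, vulnerability classes and land-area class
    shares; pairwise inter-unit significance testing (pooled two-proportion z,
    Welch t, Pearson correlation); Student's-t linear-trend testing for
    station and gridded climate series with anomaly and annual aggregation
    helpers; and a seeded synthetic-survey generator emulating a five-unit
    mixed crop-livestock survey so the whole pipeline is testable without
    access to raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
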