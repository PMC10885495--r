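Package: pivasqc
Title: Quality-Control Scoring and Benchmarking Engine for Pharmacy
    Intravenous Admixture Services
Version: 0.1.0
Authors@R:
    person("PIVAS QC", "Maintainers", email = "pivasqc@example.org",
           role = c("aut", "cre"))
Description: A reusable engine for regional quality-control assessment of
    hospital Pharmacy Intravenous Admixture Services (PIVAS). Implements a
    typed 67-item quarterly submission schema with integrity and
    cross-field audit rules, a 20-indicator evaluation matrix that maps
    raw operational data to points across five quality categories
    (total 100), regional benchmarking (per-indicator mean/max/min,
    attainment rates, radar datasets), longitudinal year-over-year
    comparison of a facility panel via paired sign-flip permutation
    tests, and a seeded synthetic facility-cohort generator so the whole
    pipeline is exercisable without access to real hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
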