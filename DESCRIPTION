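Package: pupcensus
Title: Pinniped Pup Census Pipelines: Mark-Resight Abundance, Census Tables
    and Population Trends
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating pinniped pup abundance from
    capture-mark-resight tallies (Chapman's modified Petersen estimator with
    sub-area aggregation) and replicate direct counts, assembling multi-season
    census tables with mortality and total-population conversion factors,
    fitting per-colony negative binomial trend models with reliability
    classification, and simulating colonies, observation processes and
    metapopulation trajectories for estimator validation. Developed around
    the Australian fur seal (Arctocephalus pusillus doriferus) five-yearly
    census design, but the estimators and simulators are species-agnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
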