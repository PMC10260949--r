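Package: ssbimpact
Title: Health Impact Modelling of a Sugar-Sweetened Beverage Levy Under
    Changing Trade Regimes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A stratified comparative risk assessment pipeline for
    estimating the coronary heart disease (CHD) mortality impact of a
    two-rate industry levy on sugar-sweetened beverages (SSB), with
    optional post-Brexit trade scenarios that alter the wholesale price
    of sugar. The model chains a trade-regime sugar price change, levy
    and production cost arithmetic, pass-through to consumer prices,
    socio-economically differentiated price effects on intake, and a
    potential-impact-fraction mortality engine producing deaths
    prevented or postponed (DPP) and life-years gained (LYG), stratified
    by age group, sex and deprivation quintile. Parameter uncertainty is
    propagated by seeded Monte Carlo probabilistic sensitivity analysis
    with percentile-based uncertainty intervals. Includes a calibrated
    synthetic baseline generator so the full pipeline is testable
    without restricted survey microdata.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
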