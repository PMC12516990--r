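Package: ceapipe
Title: Trial-Based Cost-Effectiveness Analysis Pipeline for Remote
    Person-Centred Care
Version: 0.1.0
Authors@R: person("PKG", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable, tested pipeline for trial-based cost-effectiveness
    analysis of a remote person-centred care add-on intervention for chronic
    heart failure and/or COPD. Generates synthetic two-arm trial registers
    (EQ-5D-3L responses, healthcare utilisation with DRG weights, drug
    dispensations, sick leave, intervention contact logs, deaths), values
    health states under configurable value sets, multiply imputes missing
    utilities, computes discounted quality-adjusted life years by
    area-under-curve, prices resource use under Swedish tariff rules
    including co-payment ceiling simulation, and produces bootstrapped
    incremental cost-effectiveness results with a full sensitivity and
    subgroup harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
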