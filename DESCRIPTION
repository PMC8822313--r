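Package: dteha
Title: Discrete-Time Event History Analysis for Response Times and Other
    Time-to-Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Life-table descriptive statistics for right-censored response
    times (discrete-time hazard, survivor, probability mass, and conditional
    accuracy functions with standard errors), discrete-time hazard regression
    on person-trial-bin data with complementary log-log or logit links,
    conditional-accuracy state-transition coding for speed-accuracy trade-off
    analysis, leave-one-participant-out jackknife inference with the
    (N-1)^2 F-correction, and a seedable generator of synthetic trial data
    from discrete hazard profiles and parametric waiting-time families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
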