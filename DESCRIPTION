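Package: itemboot
Title: Reliable Individual Change by Item Bootstrapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decides whether an individual's change between two
    administrations of a psychometric scale is statistically reliable
    when the test's psychometric properties are unknown, by
    bootstrapping the individual's own item responses (BSI) and
    comparing per-occasion confidence intervals for overlap. Includes
    the classical true-score (ETS) interval comparator based on
    Cronbach's alpha and the standard error of measurement, an ABBA
    split-half constructor of parallel forms with equivalence checks,
    percentile and bias-corrected accelerated (BCa) bootstrap
    intervals, and a simulation harness for false-positive calibration
    and power under a latent-trait ordinal response model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
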