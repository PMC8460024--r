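Package: proxinet
Title: Proximity-Sensor Social Networks and Constrained Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs roosting and foraging encounter networks of
    group-living animals from dyadic proximity-sensor streams and tests
    social hypotheses with constrained permutation methods. Includes a
    synthetic colony generator with known ground truth (latent
    differentiated relationships, kinship, type-specific departure
    schedules, nightly foraging bouts, relationship-dependent reunions);
    sensor-stream processing (encounter classification, departure and
    return detection, foraging-bout inference); dyadic network builders
    (association rates, foraging encounter time and nights, hourly
    co-foraging counts, bout overlap, degree centrality); and an
    inferential suite: social-differentiation test on data-stream
    permutations, double permutation test, QAP and MRQAP network
    regression with within-period constrained node-label permutations,
    paired day-to-night regression with bootstrapped mean slope,
    centrality-consistency test, Mantel test, and unadjusted
    repeatability (ICC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    vegan,
    lme4,
    knitr,
    rmarkdown
Config/testthat/edition: 3
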