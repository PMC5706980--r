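Package: dthaz
Title: Discrete-Time Survival Analysis for Repeated-Presentation
    Identification Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for event-history analysis of build-up (repeated
    presentation) object-identification experiments. Simulates the
    fragmented-outline build-up paradigm with a geometric fragmentation
    schedule, expands subject-by-trial outcomes into person-period format,
    estimates nonparametric discrete-time hazard and survivor functions,
    fits complementary log-log hazard regression models with polynomial
    time, recentring and cluster-robust (sandwich) inference by
    Newton-Raphson maximum likelihood, performs backward model selection
    under the hierarchical principle, and reproduces model-based predicted
    hazard, survivor and hazard-ratio tables from a published coefficient
    table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
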