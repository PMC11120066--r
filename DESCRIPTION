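Package: brachysafe
Title: Radiation Safety Assessment for Permanent I-125 Prostate Implants
Version: 0.1.0
Authors@R: person("brachysafe", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predictive modelling of the external ambient dose equivalent
    rate H*(10) around patients with permanently implanted I-125
    brachytherapy seeds.  Includes a desk-scale analog Monte Carlo photon
    transport engine with a next-event point-detector estimator for a
    Mylar-window water phantom, exponential depth-dose model fitting,
    TG-43 based absolute dose-rate prediction from air-kerma strength and
    dose-rate constant, cumulative-dose integration with radioactive
    decay, regulatory patient-release checks, a synthetic clinical-cohort
    generator, and from-scratch validation statistics (percent
    differences, two-tailed Mann-Whitney U test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
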