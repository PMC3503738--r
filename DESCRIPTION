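Package: calfpkpd
Title: Pharmacokinetics and Pain Endpoints of Intravenous Meloxicam in Dehorned Calves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-compartment IV-bolus pharmacokinetic modelling and fitting
    (curve-stripping initialization, weighted nonlinear least squares,
    AIC/SBC model selection), non-compartmental analysis (Cmax, Tmax,
    linear-trapezoid AUC/AUEC with two-group tests), and pharmacodynamic,
    behavior and performance endpoint statistics (substance P log-log
    exposure-response regression and geometric-mean-ratio contrast, lying
    behavior aggregation with pre/post contrasts, average daily gain, heart
    rate summaries) for a meloxicam dehorning trial in calves, driven by a
    seeded synthetic cohort generator that emulates the study design with
    limit-of-quantification censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
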