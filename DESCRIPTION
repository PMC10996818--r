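Package: neurosync
Title: Group-Level Neural Synchrony Analysis for fNIRS Naturalistic Paradigms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing group-level neural synchrony under naturalistic
    emotional stimulation with functional near-infrared spectroscopy (fNIRS).
    Implements the full analysis chain: preprocessing of dual-wavelength light
    intensities (channel quality control, trimming and concatenation by
    condition, zero-phase bandpass filtering, PCA-based motion correction,
    conversion to haemoglobin concentrations via the Modified Beer-Lambert Law,
    and standardised total-haemoglobin signals); pairwise and leave-one-out
    intersubject correlation (ISC) with subject-wise permutation and
    circular-shift inference; intersubject representational similarity analysis
    (IS-RSA) under Nearest-Neighbor and Anna-Karenina similarity models with
    Mantel tests and model comparison; and two-part zero-inflated Gaussian
    mixed models of bounded discrete-emotion ratings with intraclass
    correlations and marginal/conditional R-squared. A synthetic-data module
    generates cohorts, raw optical intensities, and rating tables with the
    statistical structure the analyses assume, so every stage is testable
    without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
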