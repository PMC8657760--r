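Package: acqstruct
Title: Acquiescence Correction and Five-Factor Structure of Balanced
    Socio-Emotional Skill Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the internal structure of balanced
    Likert-type socio-emotional skill inventories built from antonym item
    pairs. Estimates a per-respondent acquiescence index from balanced
    identity items, removes it by within-person centering, builds cluster
    indicator scales, fits five-factor exploratory models with oblique or
    orthogonal target rotation (an exploratory structural equation
    modelling approximation), and quantifies structure recovery with
    congruence coefficients against idealized one-hot loading targets.
    Includes a synthetic response generator with known trait structure,
    individual acquiescence shifts, and careless responders for
    truth-known validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
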