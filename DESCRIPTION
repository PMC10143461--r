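Package: otoisobol
Title: Isobolographic Analysis of Ototoxic Drug Interactions from ABR Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for fixed-dose drug-interaction studies of
    ototoxicity measured by auditory brainstem response (ABR) thresholds in
    mice. Converts pre-/post-treatment thresholds (dB SPL) into percent
    hearing-threshold-decrease effects, fits log-linear dose-response curves
    per treatment arm, inverts them to hearing-threshold-decreasing doses
    (HTDD20/HTDD50) with delta-method standard errors, computes theoretically
    additive combination doses under Loewe additivity for fixed-dose designs
    with Welch-Satterthwaite degrees of freedom, classifies interactions as
    antagonistic, additive or synergistic by Student's t-test, and reproduces
    the group-level significance structure with one-way ANOVA and Holm-Sidak
    multiple comparisons. Includes a calibrated synthetic-data generator for
    amikacin/furosemide/N-acetylcysteine designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
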