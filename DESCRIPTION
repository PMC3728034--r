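Package: beorisk
Title: Absolute Risk Projection for Breast, Endometrial, and Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects individualized absolute risks of invasive breast,
    endometrial, and ovarian cancer for white women aged 50 years or older
    from easily obtained risk factors. Relative risks are scored from
    published multiplicative categorical models, baseline hazards are built
    from registry incidence rates deflated by attributable risk, and risks
    are projected with a piecewise-constant competing-risk formula that
    accounts for mortality from other causes. Includes calibration
    (expected/observed ratios with Poisson confidence intervals) and
    discrimination (AUC with bootstrap confidence intervals) statistics, a
    piecewise-exponential cohort simulator for validation without external
    data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
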