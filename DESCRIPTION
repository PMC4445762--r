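Package: gliopi
Title: Patient-Specific Proliferation-Invasion Modeling of Glioma Growth
    and Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates glioblastoma growth with the Proliferation-Invasion
    reaction-diffusion model in spherically symmetric geometry, calibrates the
    patient-specific net invasion rate D and net proliferation rate rho from
    serial two-modality (T1Gd/T2) MRI tumor radii, builds untreated virtual
    controls and the Days Gained treatment-response score, couples the model to
    fractionated radiation therapy through the linear-quadratic dose-response
    model, simulates surgical resection and time-to-fatal-size survival
    surrogates, stratifies patients by the rho/D aggressiveness ratio, and
    generates fully synthetic virtual cohorts so every analysis is reproducible
    without patient data. All user-facing functions take and return tidy data
    frames and fitted objects ship with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
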