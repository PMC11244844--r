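Package: rcbias
Title: Simulation of Reverse-Causation Bias in First- Versus Second-Line
    Treatment Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multistate event-time simulator for quantifying reverse-causation
    (protopathic) bias in pharmacoepidemiological cohort studies that compare a
    second-line treatment to a first-line treatment whose indication shares
    symptoms with the studied outcome.  The motivating application is topical
    tacrolimus versus topical corticosteroids for atopic dermatitis with
    cutaneous T-cell lymphoma as outcome.  The package simulates latent disease
    onset, misdiagnosis, treatment initiation and switching for a large base
    population, emulates a registry-style cohort design with random
    administrative windows and left truncation, fits a one-covariate Cox model
    with a time-dependent ever-use exposure, estimates exposure-specific
    incidence rates from person-time, and summarises scenario grids over
    Monte-Carlo replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    optparse
Suggests:
    survival,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
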