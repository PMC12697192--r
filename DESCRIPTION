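Package: ctrsa
Title: Simulation and Analysis of Radiostereometric Implant Migration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for total hip arthroplasty migration
    studies measured by radiostereometric analysis (RSA) and CT-based RSA.
    Generates synthetic follow-up studies (bone marker sets, parametric
    implant models, piecewise-linear ground-truth migration), measures
    implant migration in six degrees of freedom by rigid marker
    registration and iterative-closest-point model fitting under the
    field's coordinate and sign conventions, and implements the standard
    statistics layer: double-examination precision, Bland-Altman limits of
    agreement, least-square-means method comparison, piecewise linear
    mixed-effects migration models with a 3-month breakpoint, and exact
    Clopper-Pearson confidence intervals for planned-versus-used implant
    size concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
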