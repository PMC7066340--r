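Package: mddvuln
Title: Compartmental Modelling of Adolescent Depression Vulnerability
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stratifies adolescent cohorts into high-vulnerability,
    low-vulnerability and complete-mental-health groups for major depressive
    disorder (MDD) from subjective well-being and emotional-intelligence
    questionnaire scores, estimates the rates of a three-compartment
    nonlinear ODE model (peer pressure, physical exercise, technology use)
    from cohort summaries, integrates the model, and analyses its
    equilibria and the stability of the disease-free state. Ships a
    synthetic cohort generator that reproduces the marginal structure of a
    227-adolescent study population so the whole pipeline runs end-to-end
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
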