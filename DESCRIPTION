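Package: vitcclock
Title: Kinetics, Matched Asymptotics and Rate-Constant Inference for the
    Vitamin C Iodine Clock Reaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models the household vitamin C / iodine clock reaction as a
    two-reaction mass-action system: a slow peroxide-driven oxidation of
    iodide (2A -> B, rate k0*a^2) opposed by fast inhibition of iodine by
    ascorbic acid (B + C -> 2A, rate k1*b*c). Provides the dimensional and
    dimensionless ODE systems with stiff numerical integration, the
    four-region matched-asymptotic solution with its matching constants,
    closed-form switchover (induction) times, conversion of kitchen-measure
    recipes to molar concentrations, least-squares recovery of the slow
    rate constant from observed switchover times, and a synthetic-data
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
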