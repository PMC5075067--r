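Package: meropk
Title: Plasma-CSF Population Pharmacokinetics and Dosing Simulation for
    Meropenem in Postneurosurgical Meningitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-compartment plasma-cerebrospinal-fluid (CSF) population
    pharmacokinetic model for meropenem in postneurosurgical meningitis, with
    CSF-drainage-dependent clearance. Provides exact (matrix-exponential)
    steady-state simulation of intermittent and continuous infusion regimens,
    virtual-patient sampling from published between-subject variability,
    Monte Carlo probability-of-target-attainment (PTA) evaluation against
    fT>MIC targets in plasma and CSF, synthetic sparse-sampling trial
    generation, naive-pooled maximum-likelihood fitting with bootstrap
    confidence intervals and visual predictive checks, and reporting of
    PK/PD breakpoints and dosing recommendations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
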