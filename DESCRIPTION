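Package: csfsink
Title: Compartmental Simulation of Amyloid-Beta Clearance Under
    Intrathecal and Intravenous Antibody Therapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic compartmental model of soluble cerebrospinal-fluid
    (CSF) amyloid-beta dynamics under two monoclonal-antibody delivery routes:
    continuous intrathecal pseudodelivery, modelled as an added first-order
    clearance, and monthly intravenous dosing, modelled as instantaneous
    fractional reductions between first-order decay segments. A fibrillar
    amyloid compartment expressed on the PET centiloid scale is driven by the
    soluble pool and calibrated by bounded multi-start least squares to
    milestone crossing times (PET positivity and negativity). Includes
    closed-form solutions cross-checked against adaptive ODE integration,
    threshold-crossing detection, two-arm cohort comparison and
    discontinuation/washout scenarios, sensitivity sweeps, and a virtual-cohort
    generator with noisy CSF and PET observations for estimator testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
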