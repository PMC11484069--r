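Package: burnsim
Title: Whole-Body Simulation of Burn Injury and Fluid Resuscitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of the physiological response to extensive
    burn injury and intravenous fluid resuscitation. Couples three-compartment
    volume kinetics (plasma, burnt and intact tissue water, albumin and
    extracellular sodium) with transient burn-induced perturbations, an
    algebraic circulatory-equilibrium cardiovascular block (mean systemic
    pressure, Guyton-style cardiac output/venous return intersection), a
    nephron-level kidney model with myogenic and tubuloglomerular-feedback
    autoregulation and node-wise water/sodium reabsorption, and
    renin-angiotensin-aldosterone plus antidiuretic hormone dynamics.
    Includes urine-output-titrated resuscitation protocol controllers,
    verification sweeps of renal autoregulation and pressure diuresis,
    subject-specific parameter estimation by bounded multi-start least
    squares, agreement metrics, and a synthetic virtual-patient cohort
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
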