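Package: slakin
Title: Bisubstrate Enzyme Kinetics and Mechanism Diagnostics for
    Sulfolactaldehyde Dehydrogenase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mechanistic enzymology of NAD(P)+-dependent
    bisubstrate (Bi-Bi) enzymes, built around the kinetic
    characterization of sulfolactaldehyde (SLA) dehydrogenase. Provides
    closed-form rate laws for ping-pong, ordered steady-state, rapid
    equilibrium ordered and rapid equilibrium random mechanisms together
    with their exact double-reciprocal (Lineweaver-Burk) slope and
    intercept coefficients; apparent Michaelis-Menten fitting with
    substrate-inhibition windowing and detection; IC50 dose-response
    fitting; primary and secondary double-reciprocal replot diagnostics
    (parallelism, intersection, origin tests) feeding a reproducible
    mechanism classifier cross-checked by AICc model selection;
    progress-curve endpoint analysis for stereospecificity on racemic
    substrate; and seeded synthetic-data generators emulating
    spectrophotometric initial-rate, progress-curve and dose-response
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
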