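Package: pscfit
Title: Postsynaptic Current Models with Double-Exponential Decay and a
    Newton Peak-Time Solver
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conductance-based models of AMPA and NMDA postsynaptic
    currents in which the decay phase is described by two exponentials
    (fast and slow) rather than a single weighted time constant. The
    conductance peak time of the resulting tri-exponential profile has no
    closed form and is computed by a safeguarded Newton iteration on a
    transcendental target equation. The package also provides
    voltage-clamp trace fitting (mono-, weighted- and double-exponential
    decay plus the full rise-and-decay model), RMSE-based method
    comparison, NMDA/AMPA ratio analysis with quality-control rules,
    a seeded synthetic-trace generator for validation studies, and an
    NMODL mechanism-text emitter for use with the NEURON simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
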