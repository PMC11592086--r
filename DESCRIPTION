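Package: semgrasp
Title: Compliant Grasp Simulation from Surface EMG via Muscle Models and
    Impedance Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the complete signal chain of an sEMG-driven compliant
    grasp controller for an underactuated prosthetic finger. Synthetic
    multichannel surface EMG is converted to a normalized muscle activation,
    driven through a reduced-order Huxley cross-bridge muscle model
    (Chebyshev spectral collocation plus balanced truncation) to estimate
    grasp force, and through the Hill force-velocity relation to estimate
    muscle stiffness. A fuzzy rule base maps the stiffness estimate to the
    stiffness parameter of an impedance controller that drives a
    single-actuator linkage finger against virtual objects, with Lyapunov
    instrumentation certifying closed-loop stability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
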