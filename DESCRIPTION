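Package: wkheart
Title: Lumped-Parameter Windkessel Model of the Human Left Heart and
    Systemic Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the human left heart coupled to the systemic
    circulation with a lumped (zero-dimensional, electrical-analogue)
    Windkessel model: a Frank-Starling left ventricle with twitch activation
    and law-of-Laplace wall stress, a simplified left atrium, diode valves,
    viscoelastic arterial compliances and blood inertance, integrated as a
    stiff ODE system with event-detected valve switching. Extracts per-beat
    hemodynamic indexes (isovolumic contraction duration, peak pressure-rise
    rate, ejection fraction, cardiac output, arterial pressures, stroke work
    and ventricular power), calibrates activation timing and contractility to
    externally supplied isovolumic-contraction targets, and compares steady
    cycles between control and reduced transmural-conduction-velocity
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
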