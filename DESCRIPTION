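Package: dcatfa
Title: Cardiac-Cycle-Resolved Transfer Function Analysis of Dynamic
    Cerebral Autoregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for dynamic cerebral
    autoregulation assessed with squat-stand manoeuvres under end-tidal
    CO2 clamping. Provides a synthetic cohort generator with known
    blood-pressure-to-cerebral-blood-velocity transfer parameters,
    beat-to-beat pulse decomposition (systolic, diastolic, mean),
    breath-to-breath end-tidal CO2 peak extraction, Welch cross-spectral
    transfer function analysis (coherence, phase, gain, normalized gain)
    at the forcing frequencies, and linear mixed-effects stage-by-sex
    comparison with likelihood-ratio tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
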