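Package: pplcvp
Title: Estimating Tidal Pleural Pressure Swings from Central Venous Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the tidal change in pleural pressure (dPpl)
    in passively ventilated subjects from the respiratory swing of central
    venous pressure (dCVP), calibrated by an end-expiratory occlusion test
    (kappa = dPaw/dCVP). Includes a single-compartment cardio-respiratory
    waveform simulator with known ground truth (volume-controlled ventilation,
    two chest-wall-compliance states, three intravascular-volume states),
    hold-window plateau extraction with cardiac-cycle averaging of CVP,
    validity filtering of occlusion tests, compliance partitioning
    (Crs/Ccw/CL), and method-agreement statistics (Bland-Altman limits of
    agreement and repeated-measures correlation) computed from definition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
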