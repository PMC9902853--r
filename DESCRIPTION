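Package: srtmsim
Title: Reference-Tissue Kinetic Modelling and Flow-Bias Simulation for
    Longitudinal Tau PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simplified reference tissue model (SRTM) quantification of
    dynamic tau-PET time-activity curves via basis-function receptor
    parametric mapping (RPM), yielding binding potential (BPND), the
    distribution volume ratio (DVR = BPND + 1) and relative tracer
    delivery (R1), alongside the semiquantitative SUV ratio (SUVr) over a
    late static window.  Includes a kinetic time-activity-curve simulator
    with a plasma input function, controlled cerebral-blood-flow (R1)
    perturbations and proportional frame noise; grid experiments
    quantifying the bias of SUVr relative to true DVR across binding
    levels, flow changes and SUVr scan windows; a synthetic two-timepoint
    cohort generator parameterized by group-level DVR, SUVr and R1
    distributions; and the longitudinal statistics layer (percentage
    change, annualization, paired tests, Pearson correlation,
    Bland-Altman agreement, and paired-t power and sample-size curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
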