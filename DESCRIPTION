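Package: psmcea
Title: Partitioned-Survival Cost-Effectiveness Modelling for Two-Arm Oncology Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for trial-based cost-effectiveness analysis of
    first-line regimens in metastatic non-small cell lung cancer:
    reconstruction of pseudo individual patient data from digitized
    Kaplan-Meier curves and numbers-at-risk tables, parametric survival
    fitting and extrapolation with information-criterion model selection,
    a three-state (progression-free, progressed, dead) partitioned-survival
    cohort model with discounted costs and quality-adjusted life-years,
    background mortality from period life tables, regimen costing from dose
    calendars, and one-way plus probabilistic sensitivity analysis with
    tornado, cost-effectiveness plane and acceptability-curve outputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
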