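Package: glucodiary
Title: Joint Analysis of Blinded CGM Traces and Momentary Diary Check-Ins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying how hypoglycaemia relates to self-reported
    daily functioning in insulin-treated diabetes. Fuses blinded
    continuous-glucose-monitor (CGM) traces sampled at a nominal 5-minute
    cadence with thrice-daily app check-ins: detects sensor hypoglycaemia
    episodes (<3.9 mmol/l sustained for at least 15 minutes) with severity
    subtypes, divides each 24-hour period into night-time and daytime
    intervals at check-in submission times, applies a sensor-coverage filter,
    classifies every interval by person-reported and sensor-detected
    hypoglycaemia (types A-D), and fits per-domain multilevel linear models
    with a participant random intercept, Huber-weighted robust estimation,
    a two-stage AR(1) autocorrelation adjustment, Bonferroni multiplicity
    control, and percent-change-from-intercept effect presentation. A fully
    seeded synthetic-cohort generator produces traces, check-ins and
    covariates with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nlme,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
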