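Package: actiward
Title: Accelerometer-Based Activity Monitoring and Functional Recovery
    Analysis for Hospitalized Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify posture (sedentary, standing, walking) from
    thigh-worn tri-axial accelerometer signals sampled at 25 Hz, aggregate the
    classified seconds into per-minute and per-day summaries with wear-time
    valid-day filtering, score the modified Iowa Level of Assistance Scale
    (mILAS) and its dichotomized functional-recovery-on-POD1 endpoint, and
    compare patient groups with linear and logistic regression using iterative
    change-in-estimate confounder selection. Includes a seeded synthetic-data
    generator emulating posture schedules, sensor noise, covariate structure
    and confounding of an orthopedic arthroplasty ward cohort, so the full
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
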