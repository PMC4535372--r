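Package: emrqual
Title: Completeness Assessment of Primary-Care Electronic Medical Record Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether family physicians are using their
    electronic medical record (EMR) comprehensively enough for the data to be
    usable for secondary purposes. From flat relational tables of EMR events
    (billings, progress notes, structured measurements, laboratory results,
    prescriptions, referrals, consultation letters and the cumulative patient
    profile) the package computes per-physician completeness rates for
    fourteen documentation fields, stratifies them by physician time on EMR
    and by patient time on EMR with 95 percent confidence intervals, and
    applies fixed (95 and 80 percent) and data-driven (mean minus one
    standard deviation) benchmarks to flag outlying physicians. A
    synthetic-EMR generator with configurable completeness schedules provides
    a recoverable ground truth so the whole pipeline can be exercised without
    real patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
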