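Package: adhermon
Title: Electronic Medication-Adherence Monitoring: Alarm Engine, Adherence
    Metrics, and Two-Arm Trial Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing smart-pill-box intake-event logs from
    medication-adherence trials in solid-organ transplant recipients. Implements
    the reminder-escalation feedback engine used by centralized electronic
    monitoring systems (missed-dose alarms at the break of the allowed dosing
    window with capped 30-minute escalations, plus dosage-error and
    timing-error feedback), the four electronic-monitoring adherence metrics
    (dose-taking, dose-frequency, dose-interval adherence and drug holidays),
    intrapatient coefficient of variation of immunosuppressant trough levels,
    and arm-wise trial statistics (pooled t-tests, paired t-tests, chi-squared
    with Fisher fallback) mirroring the reporting structure of two-arm
    randomized adherence trials. A discrete-event synthetic-cohort generator
    emulates twice-daily dosing behaviour, probabilistic response to escalating
    alarms, and noisy trough-level series, so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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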