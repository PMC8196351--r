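Package: alarmetrics
Title: Alarm-Quality Metrics for ICU Patient-Monitoring Audit Logs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses clinical audit logs exported from an intensive-care
    patient-monitoring central station, deidentifies them, and computes a
    five-dimension alarm-quality profile: alarm load (alarms per bed per
    day, per-parameter and per-device frequencies, criticality mix,
    24-hour temporal profiles, alarm-flood conditions), avoidable alarms
    (technical alarms), responsiveness and alarm handling (alarm
    durations from generated/terminated event pairing), sensing
    (alarm-pause usage and the proper pause-to-pause ratio,
    overmonitoring of redundant parameters), and exposure (alarm
    distribution across room types and beds). Includes a seeded
    synthetic audit-log generator with shift-dependent alarm intensity
    for testing and training, and renders quarterly-style unit alarm
    reports with tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
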