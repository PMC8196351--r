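test_that("parser handles empty, valid and malformed rows", {
  header <- "Time,Bedname,Action,Devicename"

  empty <- parse_audit_log(text = header)
  expect_equal(nrow(empty$entries), 0)
  expect_equal(nrow(empty$rejects), 0)

  good <- "2025-01-06 07:15:00,ICU-01,RED ALARM GENERATED: ABPs_HIGH,IBP"
  one <- parse_audit_log(text = c(header, good))
  expect_equal(nrow(one$entries), 1)
  expect_equal(one$entries$bed_label, "ICU-01")
  expect_equal(one$entries$timestamp, ts_utc("2025-01-06 07:15:00"))

  mixed <- parse_audit_log(text = c(
    header, good,
    "not-a-time,ICU-02,YELLOW ALARM GENERATED: HR_LOW,ECG",
    "2025-01-06 08:00:00,ICU-03,,ECG",
    "2025-01-06 08:01:00,ICU-03"
  ))
  expect_equal(nrow(mixed$entries), 1)
  expect_equal(nrow(mixed$rejects), 3)
  expect_setequal(mixed$rejects$reason,
                  c("unparseable timestamp", "empty field",
                    "wrong number of fields"))
  expect_equal(mixed$rejects$row[mixed$rejects$reason ==
                                   "unparseable timestamp"], 3L)

  expect_error(parse_audit_log(text = "Time,Bedname,Action"),
               "missing column")
})

test_that("parse/write round trip is lossless and sorts stably", {
  header <- "Time,Bedname,Action,Devicename"
  rows <- c(
    "2025-01-06 09:00:00,ICU-02,YELLOW ALARM GENERATED: HR_HIGH,ECG",
    "2025-01-06 07:15:00,ICU-01,RED ALARM GENERATED: ABPs_HIGH,IBP",
    "2025-01-06 07:15:00,ICU-03,ALARM PAUSE STARTED,MONITOR"
  )
  log <- parse_audit_log(text = c(header, rows))
  # stable sort: the two 07:15:00 rows keep file order
  expect_equal(log$entries$bed_label, c("ICU-01", "ICU-03", "ICU-02"))

  f <- withr::local_tempfile(fileext = ".csv")
  write_audit_log(log$entries, f)
  again <- parse_audit_log(file = f)
  expect_identical(log$entries, again$entries)
  # writing the sorted file reproduces it byte-identically
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_audit_log(again$entries, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("classification partitions entries and extracts alarm variables", {
  header <- "Time,Bedname,Action,Devicename"
  log <- parse_audit_log(text = c(
    header,
    "2025-01-06 07:15:00,ICU-01,RED ALARM GENERATED: ABPs_HIGH,IBP",
    "2025-01-06 07:15:20,ICU-01,RED ALARM TERMINATED: ABPs_HIGH,IBP",
    "2025-01-06 07:16:00,ICU-02,BLUE ALARM GENERATED: ECG_LEAD_OFF,ECG",
    "2025-01-06 07:17:00,ICU-02,RED ALARM GENERATED: ART_INTERRUPTED,IBP",
    "2025-01-06 07:18:00,ICU-03,ALARM PAUSE STARTED,MONITOR",
    "2025-01-06 07:19:00,ICU-04,threshold changed HR low 50 to 45,ECG"
  ))
  cl <- classify_entries(log$entries)

  # every entry lands in exactly one class; counts conserve
  expect_equal(sort(unique(cl$class)), c("alarm", "other", "pause"))
  expect_equal(sum(cl$class == "alarm") + sum(cl$class == "pause") +
                 sum(cl$class == "other"), nrow(log$entries))

  abp <- cl[cl$parameter %in% "ABPs_HIGH" & cl$kind %in% "generated", ]
  expect_equal(abp$criticality, "red")
  expect_equal(abp$device_group, "IBP")
  expect_false(abp$is_technical)

  # blue criticality is always technical; red technical parameters too
  expect_true(cl$is_technical[cl$parameter %in% "ECG_LEAD_OFF"])
  expect_true(cl$is_technical[cl$parameter %in% "ART_INTERRUPTED"])

  expect_equal(cl$pause_kind[cl$class == "pause"], "pause_started")
  expect_equal(cl$class[grepl("threshold", cl$action_raw)], "other")
})

test_that("device assignment maps known parameters and falls back to other", {
  expect_equal(assign_device_group("FREQUENCY"), "ventilator")
  expect_equal(assign_device_group("HR_LOW"), "ECG")
  expect_equal(assign_device_group(c("XYZ", "NIBP_HIGH")),
               c("other", "NIBP"))
})

test_that("deidentification preserves time structure modulo whole weeks", {
  entries <- tibble::tibble(
    timestamp = ts_utc(c("2025-01-06 07:15:00", "2025-01-11 23:59:59")),
    bed_label = c("bed7", "bed9"),
    action_raw = "ALARM PAUSE STARTED",
    device_label = "MONITOR"
  )
  ids <- c(bed7 = "A", bed9 = "B")

  expect_identical(
    deidentify_log(entries, 0, c(bed7 = "bed7", bed9 = "bed9")), entries)

  shifted <- deidentify_log(entries, 7, ids)
  expect_equal(format(shifted$timestamp, "%H:%M:%S"),
               format(entries$timestamp, "%H:%M:%S"))
  expect_equal(weekdays(shifted$timestamp), weekdays(entries$timestamp))
  expect_equal(as.numeric(diff(shifted$timestamp), units = "secs"),
               as.numeric(diff(entries$timestamp), units = "secs"))
  expect_equal(as.Date(shifted$timestamp) - as.Date(entries$timestamp),
               structure(c(7, 7), class = "difftime", units = "days"))
  expect_equal(shifted$bed_label, c("A", "B"))

  expect_error(deidentify_log(entries, 3, ids))
  expect_error(deidentify_log(entries, 7, c(bed7 = "A", bed9 = "A")),
               "injective")
  expect_error(deidentify_log(entries, 7, c(bed7 = "A")), "no pseudonym")
})
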