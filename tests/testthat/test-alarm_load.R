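test_that("alarms per bed per day handles empty and hand-counted fixtures", {
  cfg <- small_unit()
  empty <- alarms_per_bed_per_day(mk_events(character(), character()), cfg)
  expect_equal(empty$mean, 0)
  expect_equal(empty$sd, 0)

  # B1: 3 alarms day 1, 1 alarm day 2; B2: 0 and 2; B3/B4 silent
  ev <- mk_events(
    c("2025-01-06 01:00:00", "2025-01-06 02:00:00", "2025-01-06 03:00:00",
      "2025-01-07 01:00:00", "2025-01-07 02:00:00", "2025-01-07 03:00:00"),
    bed = c("B1", "B1", "B1", "B1", "B2", "B2")
  )
  res <- alarms_per_bed_per_day(ev, cfg)
  expect_equal(res$total, 6L)
  expect_equal(res$days, 2L)
  expect_equal(res$beds, 4L)
  expect_equal(res$mean, 6 / 8) # complete zero-filled grid
  counts <- sort(res$per_bed_day$n)
  expect_equal(counts, c(0, 0, 0, 0, 0, 1, 2, 3))
  # terminations are not alarms
  ev$kind <- "terminated"
  expect_equal(alarms_per_bed_per_day(ev, cfg)$total, 0L)
})

test_that("homogeneous Poisson rate is recovered within 3 standard errors", {
  sc <- synthetic_config(
    days = 4,
    parameters = default_parameter_table(total_rate = 100),
    shift_multipliers = c(morning = 1, afternoon = 1, night = 1),
    single_room_multiplier = 1,
    pause_rate_per_bed_day = 0,
    seed = 7L
  )
  log <- generate_log(sc)
  cl <- classify_entries(log, sc$unit)
  res <- alarms_per_bed_per_day(alarm_events(cl), sc$unit)
  n_bed_days <- 21 * 4
  se <- sqrt(100 * n_bed_days) / n_bed_days
  expect_lt(abs(res$mean - 100), 3 * se)
})

test_that("frequency tables rank deterministically and apply the device rule", {
  cfg <- small_unit(min_device_count = 500)
  # 499 NIBP alarms (boundary: excluded), 510 ECG, 3 unmapped
  ev <- dplyr::bind_rows(
    mk_events(rep("2025-01-06 01:00:00", 499), "B1",
              parameter = "NIBP_HIGH", criticality = "yellow"),
    mk_events(rep("2025-01-06 02:00:00", 505), "B1",
              parameter = "HR_LOW"),
    mk_events(rep("2025-01-06 02:30:00", 5), "B1",
              parameter = "HR_HIGH", criticality = "yellow"),
    mk_events(rep("2025-01-06 03:00:00", 3), "B2", parameter = "XYZ",
              criticality = "yellow")
  )
  ft <- frequency_tables(ev, cfg)
  expect_equal(ft$total, 1012L)
  expect_equal(ft$per_parameter$parameter[1:2], c("HR_LOW", "NIBP_HIGH"))

  nibp <- ft$per_device[ft$per_device$device_group == "NIBP", ]
  expect_true(all(nibp$excluded))
  expect_equal(nibp$device_total[1], 499L)
  ecg <- ft$per_device[ft$per_device$device_group == "ECG", ]
  expect_false(any(ecg$excluded))
  # excluded and unmapped devices stay in the totals
  expect_equal(sum(ft$per_device$n), ft$total)
  expect_equal(sum(ft$criticality$n), ft$total)

  # ties in parameter counts break lexicographically
  tie <- frequency_tables(dplyr::bind_rows(
    mk_events(rep("2025-01-06 01:00:00", 2), "B1", parameter = "B_PAR"),
    mk_events(rep("2025-01-06 01:00:00", 2), "B1", parameter = "A_PAR")
  ), cfg)
  expect_equal(tie$per_parameter$parameter, c("A_PAR", "B_PAR"))
})

test_that("minute profile averages clock-minute bins and conserves mass", {
  cfg <- small_unit()
  # two days, one alarm each at exactly 12:00
  ev <- mk_events(c("2025-01-06 12:00:30", "2025-01-07 12:00:01"), "B1")
  mp <- minute_bin_profile(ev, cfg)
  expect_equal(nrow(mp$profile), 1440)
  expect_equal(mp$profile$mean_count[mp$profile$minute == 720], 1.0)
  expect_equal(sum(mp$profile$mean_count), 1.0)

  # all alarms at 00:00 every day
  ev2 <- mk_events(c("2025-01-06 00:00:00", "2025-01-06 00:00:10",
                     "2025-01-07 00:00:00"), "B1")
  mp2 <- minute_bin_profile(ev2, cfg)
  expect_equal(mp2$profile$mean_count[1], 1.5)
  expect_equal(sum(mp2$profile$mean_count[-1]), 0)

  # conservation: profile mass x days = filtered stream size
  withr::with_seed(11, {
    ev3 <- random_stream(n_beds = 3, days = 3)
  })
  mp3 <- minute_bin_profile(ev3, cfg)
  expect_equal(sum(mp3$profile$mean_count) * mp3$days, nrow(ev3))
})

test_that("synthetic shift multipliers are recovered in shift means", {
  sc <- synthetic_config(days = 4, seed = 13L, pause_rate_per_bed_day = 0)
  log <- generate_log(sc)
  cl <- classify_entries(log, sc$unit)
  mp <- minute_bin_profile(alarm_events(cl), sc$unit)
  m <- stats::setNames(mp$shift_means$mean_per_min, mp$shift_means$shift)
  expect_true(m[["morning"]] > m[["afternoon"]])
  expect_true(m[["afternoon"]] > m[["night"]])
})

test_that("flood detection uses anchored tumbling bins with a count threshold", {
  cfg <- small_unit()
  base <- "2025-01-06 00:00:00"
  # 9 alarms inside one bin: below threshold
  ev9 <- mk_events(ts_utc(base) + seq(0, 240, length.out = 9), "B1")
  expect_equal(nrow(detect_alarm_floods(ev9, cfg)), 0)

  # 10 alarms at one timestamp: exactly one flood of 10
  ev10 <- mk_events(rep(base, 10), "B1")
  fl <- detect_alarm_floods(ev10, cfg)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$alarm_count, 10L)
  expect_equal(as.numeric(fl$bin_end - fl$bin_start, units = "secs"), 600)

  # bins anchor at the bed's first entry, not at clock boundaries:
  # 10 alarms spanning 07:03-07:12 fall in one anchored bin
  ev_shift <- mk_events(ts_utc("2025-01-06 07:03:00") + seq(0, 540, 60),
                        "B1")
  expect_equal(nrow(detect_alarm_floods(ev_shift, cfg)), 1)

  # beds are independent: 5 alarms on each of two beds, no flood
  ev_two <- mk_events(rep(base, 10), rep(c("B1", "B2"), 5))
  expect_equal(nrow(detect_alarm_floods(ev_two, cfg)), 0)
})

test_that("flood detector matches the brute-force bin oracle on random streams", {
  cfg <- small_unit(flood_threshold = 5)
  withr::with_seed(99, {
    for (i in 1:20) {
      ev <- random_stream(n_beds = 5, days = 2, rate_per_day = 400)
      anchors <- tapply(ev$timestamp, ev$bed, min)
      anchors <- as.POSIXct(anchors, tz = "UTC",
                            origin = "1970-01-01 00:00:00")
      got <- floods_as_bins(detect_alarm_floods(ev, cfg, anchors = anchors),
                            anchors, cfg$flood_window_s)
      want <- brute_force_floods(ev, anchors, cfg$flood_window_s,
                                 cfg$flood_threshold)
      rownames(got) <- rownames(want) <- NULL
      expect_identical(got, want)
    }
  })
})

test_that("flood summary bins sizes into half-open classes and handles emptiness", {
  floods <- tibble::tibble(
    bed = "B1",
    bin_start = ts_utc("2025-01-06 00:00:00") + (0:5) * 600,
    bin_end = ts_utc("2025-01-06 00:10:00") + (0:5) * 600,
    alarm_count = c(10L, 19L, 20L, 39L, 40L, 99L)
  )
  fs <- flood_summary(floods)
  expect_equal(fs$size_classes$n, c(2L, 2L, 2L, 0L))
  expect_equal(fs$total, 6L)
  expect_equal(fs$mean_per_day, 6)

  fs0 <- flood_summary(floods[0, ])
  expect_equal(fs0$total, 0L)
  expect_equal(fs0$mean_per_day, 0)
  expect_equal(fs0$size_classes$n, rep(0L, 4))

  # zero-flood days inside the span enter the per-day statistics
  dates <- seq(as.Date("2025-01-06"), as.Date("2025-01-08"), by = "day")
  fs3 <- flood_summary(floods, dates = dates)
  expect_equal(fs3$per_day$n, c(6L, 0L, 0L))
  expect_equal(fs3$median_per_day, 0)
  expect_equal(fs3$range_per_day, c(0L, 6L))
})

test_that("technical alarms combine blue criticality and flagged parameters", {
  cfg <- small_unit()
  ev <- dplyr::bind_rows(
    mk_events(rep("2025-01-06 01:00:00", 4), "B1",
              parameter = "ECG_LEAD_OFF", criticality = "blue",
              is_technical = TRUE),
    mk_events(rep("2025-01-06 02:00:00", 3), "B2",
              parameter = "ART_INTERRUPTED", is_technical = TRUE),
    mk_events(rep("2025-01-06 03:00:00", 5), "B2", parameter = "HR_LOW")
  )
  tm <- technical_alarm_metrics(ev, cfg)
  expect_equal(tm$total, 7L)
  expect_equal(tm$per_bed_day_mean, 7 / 4)
  expect_equal(tm$per_device$n[tm$per_device$device_group == "ECG"], 4L)
  expect_equal(tm$per_device$n[tm$per_device$device_group == "IBP"], 3L)

  none <- technical_alarm_metrics(
    mk_events("2025-01-06 01:00:00", "B1"), cfg)
  expect_equal(none$total, 0L)
})
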