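test_that("episode pairing is FIFO within (bed, parameter) and conserves events", {
  cfg <- small_unit()
  base <- ts_utc("2025-01-06 00:00:00")
  ev <- mk_events(base + c(0, 8), "B1",
                  kind = c("generated", "terminated"))
  res <- pair_alarm_episodes(ev, cfg)
  expect_equal(res$episodes$duration_s, 8)
  expect_equal(nrow(res$unmatched), 0)

  # generated with no termination: unmatched, never truncated
  open_ev <- mk_events(base, "B1")
  res2 <- pair_alarm_episodes(open_ev, cfg)
  expect_equal(nrow(res2$episodes), 0)
  expect_equal(res2$unmatched$reason, "no termination before end of data")

  # interleaved G,G,T,T at 0,1,5,9: FIFO pairs (0->5) and (1->9)
  inter <- mk_events(base + c(0, 1, 5, 9), "B1",
                     kind = c("generated", "generated",
                              "terminated", "terminated"))
  fifo <- pair_alarm_episodes(inter, cfg)
  expect_equal(sort(fifo$episodes$duration_s), c(5, 8))
  lifo <- pair_alarm_episodes(inter, small_unit(pairing = "lifo"))
  expect_equal(sort(lifo$episodes$duration_s), c(4, 9))

  # orphan termination
  orphan <- mk_events(base, "B1", kind = "terminated")
  res3 <- pair_alarm_episodes(orphan, cfg)
  expect_equal(res3$unmatched$reason, "termination with no open alarm")

  # different parameters never pair with each other
  cross <- dplyr::bind_rows(
    mk_events(base, "B1", parameter = "HR_LOW"),
    mk_events(base + 5, "B1", parameter = "HR_HIGH", kind = "terminated")
  )
  res4 <- pair_alarm_episodes(cross, cfg)
  expect_equal(nrow(res4$episodes), 0)
  expect_equal(nrow(res4$unmatched), 2)
})

test_that("pairing conserves events on a synthetic log", {
  sc <- synthetic_config(days = 2, seed = 5L)
  cl <- classify_entries(generate_log(sc), sc$unit)
  ev <- alarm_events(cl)
  res <- pair_alarm_episodes(ev, sc$unit)
  n_gen <- sum(ev$kind == "generated")
  n_term <- sum(ev$kind == "terminated")
  expect_equal(nrow(res$episodes) +
                 sum(res$unmatched$kind == "generated"), n_gen)
  expect_equal(nrow(res$episodes) +
                 sum(res$unmatched$kind == "terminated"), n_term)
  expect_true(all(res$episodes$duration_s >= 0))
})

test_that("duration summaries use the median and exclude 8-hour outliers", {
  cfg <- small_unit()
  base <- ts_utc("2025-01-06 00:00:00")
  mk_ep <- function(durs, param = "HR_LOW") {
    starts <- base + seq(0, by = 40000, length.out = length(durs))
    dplyr::bind_rows(
      mk_events(starts, "B1", parameter = param),
      mk_events(starts + durs, "B1", parameter = param,
                kind = "terminated")
    ) |> dplyr::arrange(timestamp)
  }
  eps <- pair_alarm_episodes(mk_ep(c(4, 8, 9, 9 * 3600)), cfg)$episodes
  expect_equal(sum(eps$is_outlier), 1)
  ds <- duration_summary(eps, cfg)
  expect_equal(ds$clinical$median_s, 8)
  expect_equal(ds$n_outliers, 1)
  expect_equal(ds$outliers$duration_s, 9 * 3600)
  # median invariant under any outlier cutoff at or above the max
  cfg_wide <- small_unit(duration_outlier_s = 10 * 3600)
  eps_w <- pair_alarm_episodes(mk_ep(c(4, 8, 9, 9 * 3600)), cfg_wide)$episodes
  expect_equal(duration_summary(eps_w, cfg_wide)$clinical$median_s, 8.5)
})

test_that("log-normal duration medians are recovered from the generator", {
  dm <- default_duration_models()
  dm$meanlog <- log(8)
  sc <- synthetic_config(days = 3, seed = 21L, duration_models = dm,
                         outlier_prob = 0)
  cl <- classify_entries(generate_log(sc), sc$unit)
  eps <- pair_alarm_episodes(alarm_events(cl), sc$unit)$episodes
  ds <- duration_summary(eps, sc$unit)
  expect_lt(abs(ds$clinical$median_s - 8) / 8, 0.05)
  expect_gt(ds$clinical$mean_s, ds$clinical$median_s) # right skew
})

test_that("pause extraction applies the timeout, strict-active and merge rules", {
  cfg <- small_unit()
  base <- ts_utc("2025-01-06 10:00:00")

  # explicit end at 60 s: a proper pause
  p1 <- extract_pauses(mk_markers(base + c(0, 60), "B1",
                                  c("pause_started", "pause_ended")), cfg)
  expect_true(p1$pauses$proper)
  expect_equal(p1$pauses$duration_s, 60)

  # no end marker: lasts the default 180 s, not proper
  p2 <- extract_pauses(mk_markers(base, "B1", "pause_started"), cfg)
  expect_equal(p2$pauses$duration_s, 180)
  expect_false(p2$pauses$actively_terminated)

  # end marker exactly at the default is not an active termination
  p3 <- extract_pauses(mk_markers(base + c(0, 180), "B1",
                                  c("pause_started", "pause_ended")), cfg)
  expect_false(p3$pauses$actively_terminated)

  # pauses (0-180) and (240-300): gap 60 <= 180 merges, never proper
  p4 <- extract_pauses(mk_markers(
    base + c(0, 240, 300), "B1",
    c("pause_started", "pause_started", "pause_ended")), cfg)
  expect_equal(nrow(p4$raw), 2)
  expect_equal(nrow(p4$pauses), 1)
  expect_equal(p4$pauses$merged_count, 2L)
  expect_false(p4$pauses$proper)
  expect_equal(p4$pauses$duration_s, 300)

  # end marker with no open pause goes to the orphan report
  p5 <- extract_pauses(mk_markers(base, "B1", "pause_ended"), cfg)
  expect_equal(nrow(p5$pauses), 0)
  expect_equal(nrow(p5$orphans), 1)
})

test_that("pause merging is idempotent and order-independent", {
  cfg <- small_unit()
  base <- ts_utc("2025-01-06 10:00:00")
  withr::with_seed(31, {
    starts <- sort(sample(0:5000, 30))
  })
  mks <- mk_markers(base + starts, sample(c("B1", "B2"), 30, replace = TRUE),
                    "pause_started")
  res <- extract_pauses(mks, cfg)
  merged_again <- merge_pauses(res$pauses, cfg)
  expect_equal(as.data.frame(merged_again), as.data.frame(res$pauses))

  shuffled <- mks[withr::with_seed(32, sample(nrow(mks))), ]
  res2 <- extract_pauses(shuffled, cfg)
  expect_equal(as.data.frame(res2$pauses), as.data.frame(res$pauses))
})

test_that("pause metrics report pre- and post-merge ratios and usage", {
  sc <- synthetic_config(days = 4, seed = 17L,
                         parameters = default_parameter_table(total_rate = 1),
                         pause_rate_per_bed_day = 12,
                         p_active_termination = 0.5)
  cl <- classify_entries(generate_log(sc), sc$unit)
  pauses <- extract_pauses(pause_markers(cl), sc$unit)
  pm <- pause_metrics(pauses, sc$unit)
  n <- pm$n_raw
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(pm$ratio_raw - 0.5), 3 * se)
  # merged ratio can only drop (merged records are never proper)
  expect_lte(pm$ratio, pm$ratio_raw * pm$n_raw / pm$n_merged + 1e-12)
  rate_se <- sqrt(12 / (21 * 4))
  expect_lt(abs(pm$per_bed_day_mean - 12), 3 * rate_se)
})

test_that("overmonitoring shares flag redundant respiratory-rate alarming", {
  cfg <- small_unit()
  ev <- dplyr::bind_rows(
    mk_events(rep("2025-01-06 01:00:00", 16), "B1", parameter = "RR_HIGH",
              criticality = "yellow"),
    mk_events(rep("2025-01-06 01:30:00", 84), "B1", parameter = "HR_LOW"),
    mk_events(rep("2025-01-06 02:00:00", 11), "B2",
              parameter = "FREQUENCY", criticality = "yellow"),
    mk_events(rep("2025-01-06 02:30:00", 89), "B2",
              parameter = "VENT_GENERIC", criticality = "yellow")
  )
  om <- overmonitoring_shares(ev, cfg)
  ecg <- om$rr[om$rr$device_group == "ECG", ]
  expect_equal(ecg$n_rr, 16L)
  expect_equal(ecg$share_of_device_pct, 16)
  expect_equal(ecg$share_of_all_pct, 8)
  vent <- om$rr[om$rr$device_group == "ventilator", ]
  expect_equal(vent$share_of_all_pct, 5.5)
  expect_true(om$overmonitoring_flag)

  cfg_none <- small_unit(rr_parameters = character())
  om2 <- overmonitoring_shares(ev, cfg_none)
  expect_equal(nrow(om2$rr), 0)
  expect_false(om2$overmonitoring_flag)
})
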