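#' Default synthetic alarm-parameter table
#'
#' Per-parameter base alarm rates (alarms per bed per day, before shift
#' and room multipliers) with criticalities chosen so the unit-level mix
#' matches the configured criticality shares. The parameter vocabulary
#' follows [default_device_map()]: ventilator, IBP and ECG dominate,
#' mirroring the typical surgical-ICU pattern where high/low blood
#' pressure, high respiratory rate and low heart rate are the leading
#' "bad actors".
#'
#' @param total_rate Total alarms per bed per day across all parameters.
#' @param mix Named criticality shares (must sum to 1).
#' @return Tibble: `parameter`, `criticality`, `rate` (alarms/bed/day).
#' @export
default_parameter_table <- function(total_rate = 150,
                                    mix = c(yellow = 0.79, red = 0.18,
                                            blue = 0.03)) {
  stopifnot(abs(sum(mix) - 1) < 1e-8)
  tab <- tibble::tribble(
    ~parameter, ~criticality, ~share,
    "VENT_GENERIC",    "yellow", 0.16,
    "ABPs_HIGH",       "yellow", 0.14,
    "FREQUENCY",       "yellow", 0.13,
    "ABPs_LOW",        "yellow", 0.11,
    "RR_HIGH",         "yellow", 0.07,
    "HR_HIGH",         "yellow", 0.05,
    "SPO2_LOW",        "yellow", 0.05,
    "NIBP_HIGH",       "yellow", 0.03,
    "TEMP_HIGH",       "yellow", 0.02,
    "ICP_HIGH",        "yellow", 0.02,
    "MV_LOW",          "yellow", 0.01,
    "HR_LOW",          "red",    0.08,
    "ABPm_LOW",        "red",    0.05,
    "ART_INTERRUPTED", "red",    0.02,
    "APNEA_VENT",      "red",    0.015,
    "APNEA_ECG",       "red",    0.015,
    "ECG_LEAD_OFF",    "blue",   0.022,
    "SPO2_SENSOR",     "blue",   0.005,
    "MODULE_CABLE",    "blue",   0.003
  )
  # rescale each criticality block to hit the requested mix exactly
  tab <- tab |>
    dplyr::group_by(.data$criticality) |>
    dplyr::mutate(share = .data$share / sum(.data$share) *
                    mix[.data$criticality[1]]) |>
    dplyr::ungroup() |>
    dplyr::mutate(rate = .data$share * total_rate) |>
    dplyr::select("parameter", "criticality", "rate")
  tab
}

#' Default per-device-group duration models
#'
#' Log-normal alarm-duration models per device group; the median of a
#' log-normal is `exp(meanlog)`, so the default medians (in seconds)
#' reflect the typical ordering seen on monitored units: NIBP alarms
#' (cuff cycles) longest, ECG shortest.
#'
#' @return Tibble: `device_group`, `meanlog`, `sdlog`.
#' @export
default_duration_models <- function() {
  tibble::tibble(
    device_group = c("ventilator", "ECG", "IBP", "ICP", "temperature",
                     "NIBP", "SpO2", "other"),
    meanlog = log(c(7, 4, 14, 12, 26, 64, 16, 8)),
    sdlog = rep(1, 8)
  )
}

#' Synthetic audit-log configuration
#'
#' Defines the generating model for [generate_log()]: a
#' piecewise-homogeneous Poisson process per (bed, parameter) whose
#' intensity is modulated by nursing shift (morning > afternoon > night)
#' and by room type (single-room beds alarm more), log-normal alarm
#' durations per device group with a small probability of a multi-hour
#' outlier, an alarm-pause model, and an optional technical-burst mode
#' (clustered lead-off alarms) for flood realism.
#'
#' @param unit A [unit_config()].
#' @param days Number of days to simulate.
#' @param parameters Parameter table, see [default_parameter_table()].
#' @param shift_multipliers Named positive factors applied to the base
#'   rates inside each shift.
#' @param duration_models See [default_duration_models()].
#' @param outlier_prob Probability an alarm duration is replaced by a
#'   uniform draw from `outlier_range_s` (emulating never-acknowledged
#'   alarms).
#' @param outlier_range_s Two-element range (seconds) of outlier
#'   durations.
#' @param single_room_multiplier Rate factor for single-room beds.
#' @param pause_rate_per_bed_day Pause activations per bed per day.
#' @param p_active_termination Probability a pause is actively terminated
#'   (termination time uniform on `[0, pause_default_s)`).
#' @param burst List: `enabled`, `rate_per_bed_day`, `size_mean` (mean
#'   alarms per burst above the minimum of 10), `span_s` (burst width).
#' @param start Start timestamp (a Monday by default so weekday structure
#'   is easy to reason about).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(unit = unit_config(),
                             days = 30,
                             parameters = default_parameter_table(),
                             shift_multipliers = c(morning = 1.3,
                                                   afternoon = 1.1,
                                                   night = 0.8),
                             duration_models = default_duration_models(),
                             outlier_prob = 0.002,
                             outlier_range_s = c(28800, 172800),
                             single_room_multiplier = 1.26,
                             pause_rate_per_bed_day = 10.86,
                             p_active_termination = 0.1,
                             burst = list(enabled = FALSE,
                                          rate_per_bed_day = 1,
                                          size_mean = 6,
                                          span_s = 300),
                             start = "2025-01-06 00:00:00",
                             seed = 1L) {
  stopifnot(
    days >= 0, all(parameters$rate >= 0), all(shift_multipliers > 0),
    single_room_multiplier > 0, pause_rate_per_bed_day >= 0,
    p_active_termination >= 0, p_active_termination <= 1,
    outlier_prob >= 0, outlier_prob < 1
  )
  structure(
    list(unit = unit, days = as.integer(days), parameters = parameters,
         shift_multipliers = shift_multipliers,
         duration_models = duration_models,
         outlier_prob = outlier_prob, outlier_range_s = outlier_range_s,
         single_room_multiplier = single_room_multiplier,
         pause_rate_per_bed_day = pause_rate_per_bed_day,
         p_active_termination = p_active_termination,
         burst = burst, start = start, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# shift segments within one calendar day (hours); night is split around
# midnight so each simulated day is a closed 24-hour block
.shift_segments <- function() {
  tibble::tibble(
    shift = c("night", "morning", "afternoon", "night"),
    from_h = c(0, 6, 14, 22),
    to_h = c(6, 14, 22, 24)
  )
}

#' Generate a synthetic audit log
#'
#' Simulates the canonical four-column audit log under the model in
#' [synthetic_config()]. Every alarm emits a `generated` entry and a
#' `terminated` entry after its sampled duration; pause activations emit
#' a start marker and, when actively terminated, an end marker. The
#' output parses losslessly through [parse_audit_log()] and an identical
#' seed yields a byte-identical log.
#'
#' @param config A [synthetic_config()].
#' @return Entry tibble (`timestamp`, `bed_label`, `action_raw`,
#'   `device_label`) sorted by time, with a `truth` attribute recording
#'   the generated counts (`n_alarms`, `n_burst_alarms`, `n_pauses`,
#'   `n_active_pauses`).
#' @export
generate_log <- function(config = synthetic_config()) {
  withr::local_seed(config$seed)
  u <- config$unit
  t0 <- as.POSIXct(config$start, tz = "UTC")
  if (config$days == 0) {
    out <- .empty_entries()
    attr(out, "truth") <- list(n_alarms = 0L, n_burst_alarms = 0L,
                               n_pauses = 0L, n_active_pauses = 0L)
    return(out)
  }
  bed_type <- u$room_type[u$room_of[u$beds]]
  bed_factor <- ifelse(bed_type == "single",
                       config$single_room_multiplier, 1)
  names(bed_factor) <- u$beds
  seg <- .shift_segments()
  grid <- tidyr::expand_grid(
    bed = u$beds,
    config$parameters,
    day = seq_len(config$days) - 1L,
    seg
  )
  grid$lambda <- grid$rate / 24 * (grid$to_h - grid$from_h) *
    unname(config$shift_multipliers[grid$shift]) *
    unname(bed_factor[grid$bed])
  grid$n <- stats::rpois(nrow(grid), grid$lambda)
  grid <- grid[grid$n > 0, , drop = FALSE]
  idx <- rep(seq_len(nrow(grid)), grid$n)
  ev <- grid[idx, c("bed", "parameter", "criticality", "day",
                    "from_h", "to_h")]
  ev$t <- t0 + ev$day * 86400 +
    floor(stats::runif(nrow(ev), ev$from_h * 3600, ev$to_h * 3600))
  n_base <- nrow(ev)

  # optional clustered technical bursts (lead-off episodes)
  n_burst_alarms <- 0L
  if (isTRUE(config$burst$enabled)) {
    nb <- stats::rpois(length(u$beds),
                       config$burst$rate_per_bed_day * config$days)
    bursts <- tibble::tibble(
      bed = rep(u$beds, nb),
      t0b = t0 + floor(stats::runif(sum(nb), 0, config$days * 86400)),
      size = u$flood_threshold + stats::rpois(sum(nb),
                                              config$burst$size_mean)
    )
    if (nrow(bursts)) {
      bidx <- rep(seq_len(nrow(bursts)), bursts$size)
      bev <- tibble::tibble(
        bed = bursts$bed[bidx],
        parameter = "ECG_LEAD_OFF",
        criticality = "blue",
        t = bursts$t0b[bidx] +
          floor(stats::runif(length(bidx), 0, config$burst$span_s))
      )
      ev <- dplyr::bind_rows(ev[, c("bed", "parameter", "criticality", "t")],
                             bev)
      n_burst_alarms <- nrow(bev)
    }
  }
  ev <- ev[, c("bed", "parameter", "criticality", "t")]

  # durations: log-normal per device group, occasional multi-hour outlier
  dg <- assign_device_group(ev$parameter, u)
  dm <- config$duration_models
  mi <- match(dg, dm$device_group)
  meanlog <- ifelse(is.na(mi), log(8), dm$meanlog[mi])
  sdlog <- ifelse(is.na(mi), 1, dm$sdlog[mi])
  dur <- stats::rlnorm(nrow(ev), meanlog, sdlog)
  out_mask <- stats::runif(nrow(ev)) < config$outlier_prob
  if (any(out_mask)) {
    dur[out_mask] <- stats::runif(sum(out_mask), config$outlier_range_s[1],
                                  config$outlier_range_s[2])
  }
  dur <- round(dur)

  crit_tok <- toupper(ev$criticality)
  gen_rows <- tibble::tibble(
    timestamp = ev$t,
    bed_label = ev$bed,
    action_raw = sprintf("%s ALARM GENERATED: %s", crit_tok, ev$parameter),
    device_label = dg
  )
  term_rows <- tibble::tibble(
    timestamp = ev$t + dur,
    bed_label = ev$bed,
    action_raw = sprintf("%s ALARM TERMINATED: %s", crit_tok, ev$parameter),
    device_label = dg
  )

  # pause activations
  np <- stats::rpois(length(u$beds),
                     config$pause_rate_per_bed_day * config$days)
  p_start <- t0 + floor(stats::runif(sum(np), 0, config$days * 86400))
  p_bed <- rep(u$beds, np)
  active <- stats::runif(sum(np)) < config$p_active_termination
  p_end <- p_start[active] +
    floor(stats::runif(sum(active), 0, u$pause_default_s))
  pause_rows <- dplyr::bind_rows(
    tibble::tibble(timestamp = p_start, bed_label = p_bed,
                   action_raw = "ALARM PAUSE STARTED",
                   device_label = "MONITOR"),
    tibble::tibble(timestamp = p_end, bed_label = p_bed[active],
                   action_raw = "ALARM PAUSE ENDED",
                   device_label = "MONITOR")
  )

  out <- dplyr::bind_rows(gen_rows, term_rows, pause_rows)
  out <- out[order(out$timestamp), , drop = FALSE] # stable: ties keep
  # generated-before-terminated and start-before-end construction order
  attr(out, "truth") <- list(
    n_alarms = n_base + n_burst_alarms,
    n_burst_alarms = n_burst_alarms,
    n_pauses = sum(np),
    n_active_pauses = sum(active)
  )
  out
}

#' Closed-form expectations for a synthetic configuration
#'
#' Analytic values of the headline metrics under the generating model,
#' used as recovery targets by the test suite: the expected alarm rate is
#' the summed parameter rate times the time-averaged shift multiplier
#' times the bed-averaged room factor; criticality shares equal the
#' parameter-table mix (multipliers cancel); the log-normal median is
#' `exp(meanlog)`; the proper-pause probability equals the
#' active-termination probability (uniform termination times always beat
#' the default length). Burst alarms are excluded (they are off by
#' default).
#'
#' @param config A [synthetic_config()].
#' @return List: `alarms_per_bed_day`, `criticality_shares`,
#'   `exposure_pct_diff`, `median_duration_by_device`,
#'   `proper_pause_probability`, `pauses_per_bed_day`.
#' @export
expected_metrics <- function(config = synthetic_config()) {
  u <- config$unit
  seg <- .shift_segments()
  hours <- tapply(seg$to_h - seg$from_h, seg$shift, sum)
  mean_mult <- sum(config$shift_multipliers[names(hours)] * hours) / 24
  bed_type <- u$room_type[u$room_of[u$beds]]
  n_single <- sum(bed_type == "single")
  room_factor <- (n_single * config$single_room_multiplier +
                    sum(bed_type == "double")) / length(u$beds)
  shares <- tapply(config$parameters$rate, config$parameters$criticality,
                   sum) / sum(config$parameters$rate)
  shares <- stats::setNames(as.numeric(shares), names(shares))
  list(
    alarms_per_bed_day = sum(config$parameters$rate) * mean_mult *
      room_factor,
    criticality_shares = shares,
    exposure_pct_diff = (config$single_room_multiplier - 1) * 100,
    median_duration_by_device = stats::setNames(
      exp(config$duration_models$meanlog),
      config$duration_models$device_group),
    proper_pause_probability = config$p_active_termination,
    pauses_per_bed_day = config$pause_rate_per_bed_day
  )
}
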