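#' Pair generated and terminated alarms into episodes
#'
#' Within each (bed, parameter) stream, each `generated` event is matched
#' to the earliest subsequent unconsumed `terminated` event (FIFO — the
#' queue semantics of monitor alarms; a LIFO discipline is available via
#' `config$pairing` for sensitivity analysis). The alarm duration is the
#' difference of the two log timestamps. Generated events still open at
#' the end of the data are reported unmatched rather than truncated, so
#' the data boundary cannot fabricate short durations; terminations with
#' no open alarm are reported as orphans. Durations longer than the
#' configured outlier cutoff (default 8 hours, about one shift) are
#' flagged `is_outlier`.
#'
#' @param events Classified alarm events (both kinds), see
#'   [alarm_events()].
#' @param config A [unit_config()].
#' @return List: `episodes` tibble (`bed`, `parameter`, `criticality`,
#'   `device_group`, `is_technical`, `start`, `end`, `duration_s`,
#'   `is_outlier`) and `unmatched` tibble (`bed`, `parameter`, `kind`,
#'   `timestamp`, `reason`).
#' @export
pair_alarm_episodes <- function(events, config = unit_config()) {
  ev <- events |>
    dplyr::filter(.data$class == "alarm") |>
    dplyr::arrange(.data$timestamp)
  lifo <- identical(config$pairing, "lifo")
  groups <- split(seq_len(nrow(ev)),
                  list(ev$bed, ev$parameter), drop = TRUE)
  eps <- list()
  unm <- list()
  for (g in groups) {
    kinds <- ev$kind[g]
    open <- integer(0)
    gen_i <- integer(0)
    term_i <- integer(0)
    orphan <- integer(0)
    for (j in seq_along(g)) {
      if (kinds[j] == "generated") {
        open <- c(open, g[j])
      } else if (length(open)) {
        k <- if (lifo) length(open) else 1L
        gen_i <- c(gen_i, open[k])
        term_i <- c(term_i, g[j])
        open <- open[-k]
      } else {
        orphan <- c(orphan, g[j])
      }
    }
    if (length(gen_i)) {
      eps[[length(eps) + 1L]] <- tibble::tibble(
        bed = ev$bed[gen_i],
        parameter = ev$parameter[gen_i],
        criticality = ev$criticality[gen_i],
        device_group = ev$device_group[gen_i],
        is_technical = ev$is_technical[gen_i],
        start = ev$timestamp[gen_i],
        end = ev$timestamp[term_i]
      )
    }
    bad <- c(open, orphan)
    if (length(bad)) {
      unm[[length(unm) + 1L]] <- tibble::tibble(
        bed = ev$bed[bad],
        parameter = ev$parameter[bad],
        kind = ev$kind[bad],
        timestamp = ev$timestamp[bad],
        reason = c(rep("no termination before end of data", length(open)),
                   rep("termination with no open alarm", length(orphan)))
      )
    }
  }
  episodes <- dplyr::bind_rows(eps)
  if (nrow(episodes) == 0) {
    episodes <- tibble::tibble(
      bed = character(), parameter = character(), criticality = character(),
      device_group = character(), is_technical = logical(),
      start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC")
    )
  }
  episodes <- episodes |>
    dplyr::mutate(
      duration_s = as.numeric(.data$end - .data$start, units = "secs"),
      is_outlier = .data$duration_s > config$duration_outlier_s
    ) |>
    dplyr::arrange(.data$start, .data$bed, .data$parameter)
  unmatched <- dplyr::bind_rows(unm)
  if (nrow(unmatched) == 0) {
    unmatched <- tibble::tibble(
      bed = character(), parameter = character(), kind = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"), reason = character()
    )
  }
  list(episodes = episodes, unmatched = unmatched)
}

.dur_stats <- function(x) {
  if (length(x) == 0) {
    return(tibble::tibble(n = 0L, median_s = NA_real_, mean_s = NA_real_,
                          sd_s = NA_real_, min_s = NA_real_,
                          max_s = NA_real_))
  }
  tibble::tibble(n = length(x), median_s = stats::median(x),
                 mean_s = mean(x), sd_s = stats::sd(x),
                 min_s = min(x), max_s = max(x))
}

#' Summarise alarm durations
#'
#' Alarm durations are strongly right-skewed, so the median is the
#' primary centre; mean, SD and range are emitted alongside. Durations
#' above the outlier cutoff are excluded from all summaries and reported
#' separately. Clinical (non-technical) and technical alarms are
#' summarised apart, then per criticality, per device group, and as a
#' per-clock-minute median profile of episode start times.
#'
#' @param episodes Episode tibble from [pair_alarm_episodes()].
#' @param config A [unit_config()].
#' @return List: `clinical`, `technical`, `per_criticality`,
#'   `per_device`, `minute_profile`, `outliers` (the excluded episodes),
#'   `n_outliers`.
#' @export
duration_summary <- function(episodes, config = unit_config()) {
  keep <- dplyr::filter(episodes, !.data$is_outlier)
  outliers <- dplyr::filter(episodes, .data$is_outlier)
  per_crit <- keep |>
    dplyr::group_by(.data$criticality) |>
    dplyr::reframe(.dur_stats(.data$duration_s)) |>
    dplyr::arrange(.data$criticality)
  per_dev <- keep |>
    dplyr::group_by(.data$device_group) |>
    dplyr::reframe(.dur_stats(.data$duration_s)) |>
    dplyr::arrange(dplyr::desc(.data$median_s))
  lt <- as.POSIXlt(keep$start, tz = "UTC")
  minute <- lt$hour * 60L + lt$min
  minute_profile <- tibble::tibble(minute = minute,
                                   duration_s = keep$duration_s) |>
    dplyr::group_by(.data$minute) |>
    dplyr::summarise(median_s = stats::median(.data$duration_s),
                     n = dplyr::n(), .groups = "drop")
  list(
    clinical = .dur_stats(keep$duration_s[!keep$is_technical]),
    technical = .dur_stats(keep$duration_s[keep$is_technical]),
    per_criticality = per_crit,
    per_device = per_dev,
    minute_profile = minute_profile,
    outliers = outliers,
    n_outliers = nrow(outliers)
  )
}

#' Extract alarm pauses from pause markers
#'
#' Reconstructs pause intervals per bed from `pause_started` /
#' `pause_ended` markers. A pause with no end marker lasts the monitor's
#' default length (`pause_default_s`); a pause is *actively terminated*
#' only when an explicit end marker falls strictly before the default
#' would elapse. Raw pauses re-enabled within `pause_merge_gap_s` of a
#' previous pause's end are merged into one continuous record (the
#' default length may simply have been too short for the bedside
#' procedure); a merged record is never a proper pause because at least
#' one constituent timed out. A *proper pause* is a single, actively
#' terminated pause shorter than the default length.
#'
#' @param markers Pause-marker tibble from [pause_markers()].
#' @param config A [unit_config()].
#' @return List: `pauses` (merged records: `bed`, `start`, `end`,
#'   `duration_s`, `actively_terminated`, `merged_count`, `proper`),
#'   `raw` (pre-merge records with `actively_terminated` and `proper`),
#'   `orphans` (end markers with no open pause).
#' @export
extract_pauses <- function(markers, config = unit_config()) {
  mk <- dplyr::arrange(markers, .data$timestamp)
  default_s <- config$pause_default_s
  raw <- list()
  orph <- list()
  for (b in unique(mk$bed)) {
    sub <- mk[mk$bed == b, ]
    open_start <- NULL
    starts <- as.POSIXct(character(), tz = "UTC")
    ends <- as.POSIXct(character(), tz = "UTC")
    active <- logical(0)
    close_open <- function(end_time, is_active) {
      starts <<- c(starts, open_start)
      ends <<- c(ends, end_time)
      active <<- c(active, is_active)
      open_start <<- NULL
    }
    for (j in seq_len(nrow(sub))) {
      t <- sub$timestamp[j]
      if (sub$pause_kind[j] == "pause_started") {
        if (!is.null(open_start)) close_open(open_start + default_s, FALSE)
        open_start <- t
      } else { # pause_ended
        if (is.null(open_start)) {
          orph[[length(orph) + 1L]] <- tibble::tibble(bed = b, timestamp = t)
        } else if (as.numeric(t - open_start, units = "secs") < default_s) {
          close_open(t, TRUE)
        } else {
          # marker arrived after the pause had already timed out
          close_open(open_start + default_s, FALSE)
        }
      }
    }
    if (!is.null(open_start)) close_open(open_start + default_s, FALSE)
    if (length(starts)) {
      raw[[length(raw) + 1L]] <- tibble::tibble(
        bed = b, start = starts, end = ends, actively_terminated = active
      )
    }
  }
  raw <- dplyr::bind_rows(raw)
  if (nrow(raw) == 0) {
    raw <- tibble::tibble(bed = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          actively_terminated = logical())
  }
  raw <- raw |>
    dplyr::mutate(
      duration_s = as.numeric(.data$end - .data$start, units = "secs"),
      proper = .data$actively_terminated & .data$duration_s < default_s
    ) |>
    dplyr::arrange(.data$start, .data$bed)
  merged <- merge_pauses(raw, config)
  orphans <- dplyr::bind_rows(orph)
  if (nrow(orphans) == 0) {
    orphans <- tibble::tibble(bed = character(),
                              timestamp = as.POSIXct(character(), tz = "UTC"))
  }
  list(pauses = merged, raw = raw, orphans = orphans)
}

#' Merge adjacent pause records
#'
#' Chains raw pauses per bed whose start follows the previous end by at
#' most `config$pause_merge_gap_s` seconds. Idempotent: merging an
#' already merged table leaves it unchanged.
#'
#' @param raw Raw pause tibble (`bed`, `start`, `end`,
#'   `actively_terminated`; `merged_count` optional).
#' @param config A [unit_config()].
#' @return Merged pause tibble with `merged_count` and `proper`.
#' @export
merge_pauses <- function(raw, config = unit_config()) {
  gap_s <- config$pause_merge_gap_s
  default_s <- config$pause_default_s
  if (!"merged_count" %in% names(raw)) raw$merged_count <- 1L
  if (nrow(raw) == 0) {
    return(tibble::tibble(bed = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          actively_terminated = logical(),
                          merged_count = integer(),
                          duration_s = numeric(), proper = logical()))
  }
  out <- raw |>
    dplyr::arrange(.data$bed, .data$start) |>
    dplyr::group_by(.data$bed) |>
    dplyr::mutate(
      gap = as.numeric(.data$start - dplyr::lag(.data$end), units = "secs"),
      chain = cumsum(is.na(.data$gap) | .data$gap > gap_s)
    ) |>
    dplyr::group_by(.data$bed, .data$chain) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      actively_terminated = .data$actively_terminated[dplyr::n()],
      merged_count = sum(.data$merged_count),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      duration_s = as.numeric(.data$end - .data$start, units = "secs"),
      proper = .data$actively_terminated & .data$merged_count == 1L &
        .data$duration_s < default_s
    ) |>
    dplyr::select(-"chain") |>
    dplyr::arrange(.data$start, .data$bed)
  out
}

#' Pause-usage metrics
#'
#' Usage per bed per day counts raw pause activations (each press of the
#' pause function), while the proper pause-to-pause ratio is reported
#' both before and after merging re-enabled pauses, since merging changes
#' the denominator.
#'
#' @param pauses Output of [extract_pauses()].
#' @param config A [unit_config()].
#' @param dates Optional `Date` span (defaults to the span of the raw
#'   pauses).
#' @return List: `n_raw`, `n_merged`, `n_proper`, `n_proper_raw`,
#'   `not_active_share_pct`, `ratio` (proper / merged, the "x:1"
#'   figure), `ratio_raw` (proper raw / raw), `per_bed_day_mean`,
#'   `per_bed_day_sd`.
#' @export
pause_metrics <- function(pauses, config = unit_config(), dates = NULL) {
  raw <- pauses$raw
  merged <- pauses$pauses
  if (is.null(dates)) dates <- dataset_dates(raw$start)
  beds <- union(config$beds, unique(raw$bed))
  bd <- bed_day_counts(
    tibble::tibble(timestamp = raw$start, bed = raw$bed), beds, dates
  )
  n_raw <- nrow(raw)
  n_merged <- nrow(merged)
  list(
    n_raw = n_raw,
    n_merged = n_merged,
    n_proper = sum(merged$proper),
    n_proper_raw = sum(raw$proper),
    not_active_share_pct =
      if (n_raw) percent_share(sum(!raw$actively_terminated), n_raw)
      else NA_real_,
    ratio = if (n_merged) ratio_to_one(sum(merged$proper), n_merged)
      else NA_real_,
    ratio_raw = if (n_raw) ratio_to_one(sum(raw$proper), n_raw)
      else NA_real_,
    per_bed_day_mean = if (nrow(bd)) mean(bd$n) else 0,
    per_bed_day_sd = if (nrow(bd) > 1) stats::sd(bd$n) else 0
  )
}

#' Overmonitoring of redundant parameters
#'
#' A physiological quantity alarmed by two or more device groups (e.g.
#' respiratory rate derived from both ECG impedance and the ventilator)
#' indicates overmonitoring. Emits each device group's
#' respiratory-rate-alarm share of its own alarms and of all alarms,
#' apnea counts per device group, and an overmonitoring flag raised when
#' at least two device groups each exceed `min_share` of all alarms with
#' respiratory-rate-type parameters.
#'
#' @param events Classified alarm events.
#' @param config A [unit_config()]; `rr_parameters` and
#'   `apnea_parameters` name the parameter-to-device assignments.
#' @param min_share Minimum share (fraction of all alarms) for a device
#'   group to count towards the flag.
#' @return List: `rr` tibble (`device_group`, `n_rr`, `n_device`,
#'   `share_of_device_pct`, `share_of_all_pct`), `apnea` tibble,
#'   `overmonitoring_flag`.
#' @export
overmonitoring_shares <- function(events, config = unit_config(),
                                  min_share = 0.05) {
  gen <- dplyr::filter(events, .data$kind == "generated")
  total <- nrow(gen)
  rr_par <- config$rr_parameters
  if (length(rr_par) == 0 || total == 0) {
    return(list(rr = tibble::tibble(device_group = character(),
                                    n_rr = integer(), n_device = integer(),
                                    share_of_device_pct = numeric(),
                                    share_of_all_pct = numeric()),
                apnea = tibble::tibble(device_group = character(),
                                       n = integer()),
                overmonitoring_flag = FALSE))
  }
  rr <- tibble::tibble(parameter = names(rr_par),
                       device_group = unname(rr_par)) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_rr = sum(gen$parameter == .data$parameter),
      n_device = sum(gen$device_group == .data$device_group)
    ) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$device_group) |>
    dplyr::summarise(n_rr = sum(.data$n_rr),
                     n_device = .data$n_device[1], .groups = "drop") |>
    dplyr::mutate(
      share_of_device_pct = percent_share(.data$n_rr,
                                          pmax(.data$n_device, 1L)),
      share_of_all_pct = percent_share(.data$n_rr, total)
    )
  ap_par <- config$apnea_parameters
  apnea <- tibble::tibble(parameter = names(ap_par),
                          device_group = unname(ap_par)) |>
    dplyr::rowwise() |>
    dplyr::mutate(n = sum(gen$parameter == .data$parameter)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$device_group) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  flag <- sum(rr$share_of_all_pct / 100 > min_share) >= 2
  list(rr = rr, apnea = apnea, overmonitoring_flag = flag)
}
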