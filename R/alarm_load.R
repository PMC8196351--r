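#' Alarms per bed per day
#'
#' Counts generated alarms per (bed, calendar day) over the full observed
#' day span, zero-filling bed-days without alarms, and summarises the
#' distribution. Terminations are not alarms and are ignored. Partially
#' observed edge days enter as-is.
#'
#' Two means are reported: `mean` is the mean of the per-bed-day counts
#' (equals `total / (beds * days)` when the grid is complete, which the
#' zero-filling guarantees) and `sd` their standard deviation over
#' bed-days; `sd_daily` is the SD of the daily per-bed means across
#' calendar days (both variants are emitted because per-day spread can be
#' summarised either way).
#'
#' @param events Classified alarm events (see [alarm_events()]); only
#'   rows with `kind == "generated"` are counted.
#' @param config A [unit_config()]; supplies the bed roster.
#' @param dates Optional `Date` vector fixing the day span (defaults to
#'   the span of `events`).
#' @return List: `per_bed_day` tibble (`bed`, `day`, `n`), `total`,
#'   `beds`, `days`, `mean`, `sd`, `mean_daily`, `sd_daily`.
#' @export
alarms_per_bed_per_day <- function(events, config = unit_config(),
                                   dates = NULL) {
  gen <- dplyr::filter(events, .data$kind == "generated")
  if (is.null(dates)) dates <- dataset_dates(gen$timestamp)
  beds <- union(config$beds, unique(gen$bed))
  if (length(dates) == 0) {
    return(list(per_bed_day = bed_day_counts(gen, beds, dates),
                total = 0L, beds = length(beds), days = 0L,
                mean = 0, sd = 0, mean_daily = 0, sd_daily = 0))
  }
  bd <- bed_day_counts(gen, beds, dates)
  daily <- bd |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(mean_n = mean(.data$n), .groups = "drop")
  list(
    per_bed_day = bd,
    total = nrow(gen),
    beds = length(beds),
    days = length(dates),
    mean = mean(bd$n),
    sd = stats::sd(bd$n),
    mean_daily = mean(daily$mean_n),
    sd_daily = stats::sd(daily$mean_n)
  )
}

#' Alarm frequency tables
#'
#' Ranked per-parameter counts ("bad actors"), per-device-by-criticality
#' counts with the minimum-frequency reporting rule, and criticality
#' totals with per-day means. Device groups whose cumulative alarm count
#' falls below `config$min_device_count` are flagged `excluded` — they
#' are left out of device-level reporting but always remain in the
#' overall totals.
#'
#' @inheritParams alarms_per_bed_per_day
#' @return List: `per_parameter` (descending by count, ties broken
#'   lexicographically), `per_device` (device x criticality counts,
#'   `device_total`, `excluded`), `criticality` (count, `per_day_mean`,
#'   `share_pct`), `total`, `days`.
#' @export
frequency_tables <- function(events, config = unit_config(), dates = NULL) {
  gen <- dplyr::filter(events, .data$kind == "generated")
  if (is.null(dates)) dates <- dataset_dates(gen$timestamp)
  n_days <- length(dates)
  total <- nrow(gen)

  per_parameter <- gen |>
    dplyr::count(.data$parameter, .data$criticality,
                 .data$device_group, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$parameter)

  per_device <- gen |>
    dplyr::count(.data$device_group, .data$criticality, name = "n") |>
    dplyr::group_by(.data$device_group) |>
    dplyr::mutate(device_total = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(excluded = .data$device_total < config$min_device_count) |>
    dplyr::arrange(dplyr::desc(.data$device_total), .data$device_group,
                   .data$criticality)

  criticality <- gen |>
    dplyr::count(.data$criticality, name = "n") |>
    dplyr::mutate(
      per_day_mean = .data$n / max(n_days, 1L),
      share_pct = percent_share(.data$n, max(total, 1L))
    ) |>
    dplyr::arrange(dplyr::desc(.data$n))

  list(per_parameter = per_parameter, per_device = per_device,
       criticality = criticality, total = total, days = n_days)
}

#' 24-hour minute-bin alarm profile
#'
#' Average number of alarms in each of the 1440 one-minute clock bins
#' (00:00 through 23:59), pooled across beds: bin value = alarms falling
#' in that clock minute across all days, divided by the number of days.
#' Per-shift means are taken over the bins inside each shift window,
#' excluding the configured handover minutes at the start of each shift.
#'
#' @inheritParams alarms_per_bed_per_day
#' @param device_filter Optional character vector of device groups to
#'   restrict to.
#' @param dates Day span used as the averaging denominator; defaults to
#'   the span of the (unfiltered) events so that conservation holds:
#'   `sum(profile$mean_count) * days` equals the filtered stream size.
#' @return List: `profile` tibble (`minute` 0..1439, `count`,
#'   `mean_count`, `shift`, `handover`), `shift_means` tibble, `days`.
#' @export
minute_bin_profile <- function(events, config = unit_config(),
                               device_filter = NULL, dates = NULL) {
  gen <- dplyr::filter(events, .data$kind == "generated")
  if (is.null(dates)) dates <- dataset_dates(gen$timestamp)
  n_days <- length(dates)
  if (!is.null(device_filter)) {
    gen <- dplyr::filter(gen, .data$device_group %in% device_filter)
  }
  minute <- as.POSIXlt(gen$timestamp, tz = "UTC")
  minute <- minute$hour * 60L + minute$min
  counts <- tabulate(minute + 1L, nbins = 1440L)
  profile <- tibble::tibble(
    minute = 0:1439,
    count = counts,
    mean_count = if (n_days > 0) counts / n_days else 0 * counts,
    shift = shift_of_minute(0:1439, config$shifts),
    handover = in_handover(0:1439, config$shifts)
  )
  shift_means <- profile |>
    dplyr::filter(!.data$handover) |>
    dplyr::group_by(.data$shift) |>
    dplyr::summarise(mean_per_min = mean(.data$mean_count),
                     sd_per_min = stats::sd(.data$mean_count),
                     .groups = "drop")
  list(profile = profile, shift_means = shift_means, days = n_days)
}

#' Detect alarm-flood conditions
#'
#' Splits each bed's generated alarms into fixed (tumbling) bins of
#' `config$flood_window_s` seconds anchored at that bed's first log
#' entry, and reports every bin holding at least
#' `config$flood_threshold` alarms as an alarm flood. Beds are
#' independent. A sliding variant (a candidate window starting at each
#' alarm) is available for sensitivity analysis.
#'
#' @inheritParams alarms_per_bed_per_day
#' @param anchors Optional named `POSIXct` vector giving each bed's
#'   anchor time (normally the bed's first entry in the full log,
#'   including non-alarm entries); beds missing from `anchors` are
#'   anchored at their first alarm in `events`.
#' @param sliding If `TRUE`, use overlapping windows starting at each
#'   alarm instead of tumbling bins (off by default).
#' @return Tibble of flood windows: `bed`, `bin_start`, `bin_end`,
#'   `alarm_count`.
#' @export
detect_alarm_floods <- function(events, config = unit_config(),
                                anchors = NULL, sliding = FALSE) {
  gen <- dplyr::filter(events, .data$kind == "generated")
  w <- config$flood_window_s
  out <- lapply(split(gen$timestamp, gen$bed), function(ts) ts)
  beds <- names(out)
  res <- vector("list", length(beds))
  for (i in seq_along(beds)) {
    ts <- sort(out[[i]])
    anchor <- if (!is.null(anchors) && beds[i] %in% names(anchors)) {
      anchors[[beds[i]]]
    } else {
      ts[1]
    }
    if (sliding) {
      off <- as.numeric(ts - anchor, units = "secs")
      cnt <- vapply(off, function(o) sum(off >= o & off < o + w), integer(1))
      keep <- cnt >= config$flood_threshold
      res[[i]] <- tibble::tibble(
        bed = beds[i],
        bin_start = anchor + off[keep],
        bin_end = anchor + off[keep] + w,
        alarm_count = cnt[keep]
      )
    } else {
      bin <- floor(as.numeric(ts - anchor, units = "secs") / w)
      tab <- table(bin)
      keep <- tab >= config$flood_threshold
      idx <- as.numeric(names(tab)[keep])
      res[[i]] <- tibble::tibble(
        bed = beds[i],
        bin_start = anchor + idx * w,
        bin_end = anchor + (idx + 1) * w,
        alarm_count = as.integer(tab[keep])
      )
    }
  }
  res <- dplyr::bind_rows(res)
  if (nrow(res) == 0) {
    res <- tibble::tibble(bed = character(),
                          bin_start = as.POSIXct(character(), tz = "UTC"),
                          bin_end = as.POSIXct(character(), tz = "UTC"),
                          alarm_count = integer())
  }
  dplyr::arrange(res, .data$bin_start, .data$bed)
}

#' Summarise alarm floods
#'
#' Per-calendar-day flood counts (days without floods count zero) with
#' mean/SD/median/range, and a flood-size histogram over the half-open
#' classes `[10,20)`, `[20,40)`, `[40,100)`, `[100,Inf)` (boundaries
#' follow the flood threshold; configurable via `breaks`).
#'
#' @param floods Output of [detect_alarm_floods()].
#' @param dates `Date` vector of the observation days (so zero-flood
#'   days enter the statistics); defaults to the span of `floods`.
#' @param breaks Lower class boundaries for the size histogram.
#' @return List: `total`, `per_day` tibble, `mean_per_day`, `sd_per_day`,
#'   `median_per_day`, `range_per_day`, `size_classes` tibble.
#' @export
flood_summary <- function(floods, dates = NULL,
                          breaks = c(10, 20, 40, 100)) {
  if (is.null(dates)) dates <- dataset_dates(floods$bin_start)
  if (length(dates) == 0) {
    per_day <- tibble::tibble(day = dates, n = integer())
    return(list(total = 0L, per_day = per_day,
                mean_per_day = 0, sd_per_day = 0,
                median_per_day = 0, range_per_day = c(0, 0),
                size_classes = tibble::tibble(
                  class = .size_class_labels(breaks), n = 0L)))
  }
  daily <- tibble::tibble(day = dates) |>
    dplyr::left_join(
      floods |>
        dplyr::mutate(day = as.Date(.data$bin_start, tz = "UTC")) |>
        dplyr::count(.data$day),
      by = "day") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
  cls <- cut(floods$alarm_count, c(breaks, Inf), right = FALSE,
             labels = .size_class_labels(breaks))
  tab <- table(cls) # factor table: every class present, zeros kept
  size_classes <- tibble::tibble(class = levels(cls),
                                 n = as.integer(tab[levels(cls)]))
  list(
    total = nrow(floods),
    per_day = daily,
    mean_per_day = mean(daily$n),
    sd_per_day = stats::sd(daily$n),
    median_per_day = stats::median(daily$n),
    range_per_day = range(daily$n),
    size_classes = size_classes
  )
}

.size_class_labels <- function(breaks) {
  upper <- c(breaks[-1], Inf)
  ifelse(is.finite(upper),
         sprintf("[%g,%g)", breaks, upper),
         sprintf(">=%g", breaks))
}

#' Technical (avoidable) alarm metrics
#'
#' Technical alarms are the blue-criticality alarms plus the configured
#' technical parameters of any criticality (e.g. an interrupted arterial
#' measurement alarms red but is equipment-caused). They are considered
#' avoidable.
#'
#' @inheritParams alarms_per_bed_per_day
#' @return List: `total`, `per_bed_day_mean`, `per_bed_day_sd`,
#'   `per_device` counts by criticality, `per_parameter` ranked counts.
#' @export
technical_alarm_metrics <- function(events, config = unit_config(),
                                    dates = NULL) {
  gen <- dplyr::filter(events, .data$kind == "generated")
  if (is.null(dates)) dates <- dataset_dates(gen$timestamp)
  tech <- dplyr::filter(gen, .data$is_technical)
  beds <- union(config$beds, unique(gen$bed))
  bd <- bed_day_counts(tech, beds, dates)
  list(
    total = nrow(tech),
    per_bed_day_mean = if (nrow(bd)) mean(bd$n) else 0,
    per_bed_day_sd = if (nrow(bd) > 1) stats::sd(bd$n) else 0,
    per_device = tech |>
      dplyr::count(.data$device_group, .data$criticality, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n)),
    per_parameter = tech |>
      dplyr::count(.data$parameter, .data$criticality, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$parameter)
  )
}
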