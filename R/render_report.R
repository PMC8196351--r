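.fmt <- function(x, digits = 2) {
  ifelse(is.na(x), "-", formatC(x, format = "f", digits = digits))
}

.md_table <- function(df, digits = 2) {
  df <- as.data.frame(df)
  for (i in seq_along(df)) {
    if (is.numeric(df[[i]]) && !is.integer(df[[i]])) {
      df[[i]] <- .fmt(df[[i]], digits)
    }
  }
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  if (nrow(df) == 0) {
    return(c(header, sep, paste("|", paste(rep(" ", ncol(df)),
                                           collapse = " | "), "|")))
  }
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "),
                                         "|"))
  c(header, sep, rows)
}

#' Render a unit alarm report
#'
#' Writes a quarterly-style alarm report from a computed
#' [run_pipeline()] bundle: a markdown body holding every dimension's
#' metric tables, plain CSV data tables for each figure (so values can
#' be checked without reading pixels), and optionally the figures as
#' PNGs. Every number in the report is taken from the bundle; the
#' renderer computes nothing. Rendering the same bundle twice produces a
#' byte-identical markdown body.
#'
#' Figures: ranked alarm parameters coloured by criticality, alarms per
#' device by criticality, the 24-hour minute-profile with shift bands
#' (handover periods left blank), the flood timeline over the day, the
#' 24-hour median-duration profile, and median duration versus alarm
#' count per device.
#'
#' @param bundle A `metrics_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param figures Render PNG figures (set `FALSE` for text-only output).
#' @param top_parameters How many parameters to show in the ranked chart.
#' @return Path of the markdown report, invisibly.
#' @export
render_report <- function(bundle, dir, figures = TRUE,
                          top_parameters = 20) {
  dir.create(file.path(dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  if (figures) dir.create(file.path(dir, "figures"), showWarnings = FALSE)

  ld <- bundle$load
  tabs <- list(
    parameter_frequency = utils::head(ld$frequency$per_parameter,
                                      top_parameters),
    device_criticality = ld$frequency$per_device,
    criticality_mix = ld$frequency$criticality,
    minute_profile = ld$minute_profile$profile,
    flood_windows = ld$floods,
    flood_size_classes = ld$flood_summary$size_classes,
    duration_per_device = bundle$handling$duration_summary$per_device,
    duration_minute_profile =
      bundle$handling$duration_summary$minute_profile,
    exposure_room_type = bundle$exposure$room_type$per_type,
    overmonitoring_rr = bundle$sensing$overmonitoring$rr
  )
  for (nm in names(tabs)) {
    utils::write.csv(as.data.frame(tabs[[nm]]),
                     file.path(dir, "tables", paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (figures) .render_figures(bundle, file.path(dir, "figures"),
                               top_parameters)

  abd <- ld$per_bed_day
  fs <- ld$flood_summary
  pm <- bundle$sensing$pause_metrics
  ds <- bundle$handling$duration_summary
  ba <- bundle$exposure$beds_above
  rt <- bundle$exposure$room_type
  lines <- c(
    "# Unit alarm report",
    "",
    sprintf("Dataset: %d log entries (%d alarm, %d pause, %d other) over %d days.",
            bundle$provenance$n_entries,
            bundle$provenance$n_by_class$alarm,
            bundle$provenance$n_by_class$pause,
            bundle$provenance$n_by_class$other,
            bundle$provenance$days),
    sprintf("Software version %s; config hash %s.",
            bundle$provenance$version, bundle$provenance$config_hash),
    if (isTRUE(bundle$warnings$empty_log))
      "**Warning: the log contained no entries; all panels are empty.**",
    "",
    "## Alarm load",
    "",
    sprintf("- Alarms per bed per day: mean %s (SD %s); total %d alarms, %d beds, %d days.",
            .fmt(abd$mean, 1), .fmt(abd$sd, 1), abd$total, abd$beds,
            abd$days),
    sprintf("- Alarm floods (>= threshold alarms per bin): %d total; per day mean %s (SD %s), median %s, range %d-%d.",
            fs$total, .fmt(fs$mean_per_day), .fmt(fs$sd_per_day),
            .fmt(fs$median_per_day, 1), fs$range_per_day[1],
            fs$range_per_day[2]),
    "",
    "### Criticality mix",
    "",
    .md_table(ld$frequency$criticality),
    "",
    "### Most frequent alarm parameters",
    "",
    .md_table(tabs$parameter_frequency),
    "",
    "### Alarms per device",
    "",
    "Device groups below the minimum reporting count are flagged `excluded`",
    "and appear only in overall totals.",
    "",
    .md_table(ld$frequency$per_device),
    "",
    "### Flood size classes",
    "",
    .md_table(fs$size_classes),
    "",
    "### Per-shift alarm intensity (alarms/minute, handover excluded)",
    "",
    .md_table(ld$minute_profile$shift_means, 3),
    "",
    "## Avoidable alarms",
    "",
    sprintf("- Technical alarms: %d total, %s per bed per day (SD %s).",
            bundle$avoidable$total, .fmt(bundle$avoidable$per_bed_day_mean, 1),
            .fmt(bundle$avoidable$per_bed_day_sd, 1)),
    "",
    .md_table(bundle$avoidable$per_device),
    "",
    "## Responsiveness and alarm handling",
    "",
    sprintf("- Clinical alarms: median duration %s s (n=%d); technical: median %s s (n=%d); %d episodes above the outlier cutoff were excluded.",
            .fmt(ds$clinical$median_s, 0), ds$clinical$n,
            .fmt(ds$technical$median_s, 0), ds$technical$n, ds$n_outliers),
    "",
    "### Durations per device",
    "",
    .md_table(ds$per_device, 1),
    "",
    "### Durations per criticality",
    "",
    .md_table(ds$per_criticality, 1),
    "",
    "## Sensing",
    "",
    sprintf("- Pause activations: %d raw (%s per bed per day, SD %s); %d after merging re-enabled pauses.",
            pm$n_raw, .fmt(pm$per_bed_day_mean), .fmt(pm$per_bed_day_sd),
            pm$n_merged),
    sprintf("- Not actively terminated: %s%% of raw pauses.",
            .fmt(pm$not_active_share_pct, 0)),
    sprintf("- Proper pause-to-pause ratio: %s:1 (merged; %s:1 before merging).",
            .fmt(pm$ratio), .fmt(pm$ratio_raw)),
    sprintf("- Overmonitoring flag: %s.",
            ifelse(bundle$sensing$overmonitoring$overmonitoring_flag,
                   "raised (>= 2 device groups alarm the respiratory rate)",
                   "not raised")),
    "",
    .md_table(bundle$sensing$overmonitoring$rr, 1),
    "",
    "## Exposure",
    "",
    sprintf("- Single-room beds issue %s%% more alarms per bed than double-room beds (red: %s%%, yellow: %s%%).",
            .fmt(rt$pct_diff, 0),
            .fmt(rt$pct_diff_by_criticality[["red"]], 0),
            .fmt(rt$pct_diff_by_criticality[["yellow"]], 0)),
    sprintf("- On average %s beds (%s%% of the unit) exceeded the unit's daily average, issuing %s%% of daily alarms.",
            .fmt(ba$mean_beds_above, 1), .fmt(ba$pct_beds_above, 0),
            .fmt(ba$mean_share_pct, 0)),
    "",
    .md_table(rt$per_type, 1),
    ""
  )
  out <- file.path(dir, "report.md")
  writeLines(lines, out, useBytes = TRUE)
  invisible(out)
}

.shift_bands <- function(shifts = default_shifts()) {
  # shaded shift bands with the handover minutes left blank
  tibble::tibble(
    xmin = ifelse(shifts$start_min + shifts$handover_min >= 1440,
                  shifts$start_min + shifts$handover_min - 1440,
                  shifts$start_min + shifts$handover_min),
    xmax = ifelse(shifts$end_min > 1440, shifts$end_min - 1440,
                  shifts$end_min),
    shift = shifts$shift
  )
}

.render_figures <- function(bundle, dir, top_parameters) {
  crit_cols <- c(red = "#c0392b", yellow = "#d4a017", blue = "#2c5f8a")
  save_fig <- function(p, name, w = 7, h = 4.5) {
    ggplot2::ggsave(file.path(dir, name), p, width = w, height = h,
                    dpi = 120)
  }
  pf <- utils::head(bundle$load$frequency$per_parameter, top_parameters)
  if (nrow(pf)) {
    p <- ggplot2::ggplot(pf, ggplot2::aes(
      x = stats::reorder(.data$parameter, .data$n),
      y = .data$n, fill = .data$criticality)) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::scale_fill_manual(values = crit_cols) +
      ggplot2::labs(x = NULL, y = "alarms",
                    title = "Most frequent alarm parameters") +
      ggplot2::theme_minimal()
    save_fig(p, "parameter_frequency.png", h = 6)
  }
  pd <- dplyr::filter(bundle$load$frequency$per_device, !.data$excluded)
  if (nrow(pd)) {
    p <- ggplot2::ggplot(pd, ggplot2::aes(
      x = stats::reorder(.data$device_group, .data$device_total),
      y = .data$n, fill = .data$criticality)) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::scale_fill_manual(values = crit_cols) +
      ggplot2::labs(x = NULL, y = "alarms",
                    title = "Alarms per device by criticality") +
      ggplot2::theme_minimal()
    save_fig(p, "device_criticality.png")
  }
  bands <- .shift_bands()
  prof <- bundle$load$minute_profile$profile
  if (sum(prof$count) > 0) {
    # centred rolling mean as the documented trend line
    k <- 31
    trend <- stats::filter(prof$mean_count, rep(1 / k, k), sides = 2)
    prof$trend <- as.numeric(trend)
    p <- ggplot2::ggplot(prof, ggplot2::aes(.data$minute,
                                            .data$mean_count)) +
      ggplot2::geom_rect(
        data = bands, inherit.aes = FALSE, alpha = 0.12,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf)) +
      ggplot2::geom_point(size = 0.4, alpha = 0.4) +
      ggplot2::geom_line(ggplot2::aes(y = .data$trend), colour = "#2c5f8a",
                         linewidth = 0.8, na.rm = TRUE) +
      ggplot2::labs(x = "minute of day", y = "mean alarms/minute",
                    title = "24-hour alarm profile (31-min rolling mean)") +
      ggplot2::theme_minimal()
    save_fig(p, "minute_profile.png")
  }
  fl <- bundle$load$floods
  if (nrow(fl)) {
    lt <- as.POSIXlt(fl$bin_start, tz = "UTC")
    fl$tod_bin <- (lt$hour * 60L + lt$min) %/% 10L * 10L
    fl_tab <- dplyr::count(fl, .data$tod_bin)
    p <- ggplot2::ggplot(fl_tab, ggplot2::aes(.data$tod_bin, .data$n)) +
      ggplot2::geom_rect(
        data = bands, inherit.aes = FALSE, alpha = 0.12,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "minute of day (10-min bins)",
                    y = "alarm floods started",
                    title = "Alarm floods over the day") +
      ggplot2::theme_minimal()
    save_fig(p, "flood_timeline.png")
  }
  dm <- bundle$handling$duration_summary$minute_profile
  if (nrow(dm)) {
    p <- ggplot2::ggplot(dm, ggplot2::aes(.data$minute, .data$median_s)) +
      ggplot2::geom_rect(
        data = bands, inherit.aes = FALSE, alpha = 0.12,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf)) +
      ggplot2::geom_point(size = 0.4, alpha = 0.5) +
      ggplot2::labs(x = "minute of day", y = "median duration (s)",
                    title = "Median alarm duration over the day") +
      ggplot2::theme_minimal()
    save_fig(p, "duration_profile.png")
  }
  dd <- bundle$handling$duration_summary$per_device
  counts <- bundle$load$frequency$per_device |>
    dplyr::group_by(.data$device_group) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop")
  dd <- dplyr::inner_join(dd, counts, by = "device_group")
  if (nrow(dd)) {
    p <- ggplot2::ggplot(dd, ggplot2::aes(.data$total, .data$median_s)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_text(ggplot2::aes(label = .data$device_group),
                         vjust = -0.8, size = 3) +
      ggplot2::labs(x = "alarms issued", y = "median duration (s)",
                    title = "Median duration vs alarm count per device") +
      ggplot2::theme_minimal()
    save_fig(p, "duration_vs_count.png")
  }
  invisible(NULL)
}
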