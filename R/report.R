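#' Run the full alarm-analysis pipeline
#'
#' Parses one or more audit-log files (or takes an already parsed entry
#' table), classifies the entries, and computes every alarm-quality
#' dimension: alarm load, avoidable (technical) alarms, responsiveness
#' and alarm handling, sensing, and exposure. Flood bins are anchored at
#' each bed's first entry of the combined, sorted log (so concatenating
#' files is equivalent to analysing them as one dataset). The day span
#' used for all per-day denominators is the calendar span of the
#' generated alarms.
#'
#' @param files Character vector of audit-log paths.
#' @param entries Alternatively, an entry tibble (as from
#'   [parse_audit_log()] or [generate_log()]).
#' @param config A [unit_config()].
#' @param dialect An [audit_dialect()].
#' @return A `metrics_bundle`: list with elements `load`, `avoidable`,
#'   `handling`, `sensing`, `exposure`, `warnings`, `provenance`.
#' @export
run_pipeline <- function(files = NULL, entries = NULL,
                         config = unit_config(),
                         dialect = audit_dialect()) {
  rejects <- .empty_rejects()
  if (is.null(entries)) {
    stopifnot(length(files) >= 1)
    parsed <- lapply(files, parse_audit_log, dialect = dialect)
    entries <- dplyr::bind_rows(lapply(parsed, `[[`, "entries"))
    rejects <- dplyr::bind_rows(lapply(parsed, `[[`, "rejects"))
    entries <- entries[order(entries$timestamp), , drop = FALSE]
  }
  cl <- classify_entries(entries, config, dialect)
  ev <- alarm_events(cl)
  mk <- pause_markers(cl)
  gen <- dplyr::filter(ev, .data$kind == "generated")
  dates <- dataset_dates(gen$timestamp)

  # flood bins anchor at each bed's first entry of any kind
  if (nrow(entries)) {
    anchors <- tapply(entries$timestamp, entries$bed_label, min)
    anchors <- as.POSIXct(anchors, tz = "UTC",
                          origin = "1970-01-01 00:00:00")
  } else {
    anchors <- NULL
  }

  abd <- alarms_per_bed_per_day(ev, config, dates)
  freq <- frequency_tables(ev, config, dates)
  top3 <- setdiff(unique(freq$per_device$device_group[
    !freq$per_device$excluded]), "other")
  top3 <- utils::head(top3, 3)
  profile <- minute_bin_profile(ev, config, dates = dates)
  profile_top3 <- lapply(stats::setNames(top3, top3), function(d) {
    minute_bin_profile(ev, config, device_filter = d, dates = dates)
  })
  floods <- detect_alarm_floods(ev, config, anchors = anchors)
  fsum <- flood_summary(floods, dates)
  tech <- technical_alarm_metrics(ev, config, dates)

  pairing <- pair_alarm_episodes(ev, config)
  dsum <- duration_summary(pairing$episodes, config)
  pauses <- extract_pauses(mk, config)
  psum <- pause_metrics(pauses, config, dates)
  over <- overmonitoring_shares(ev, config)

  expo <- room_type_exposure(ev, config, dates)
  above <- beds_above_average(ev, config, dates)

  n_by_class <- table(factor(cl$class, c("alarm", "pause", "other")))
  bundle <- structure(
    list(
      load = list(per_bed_day = abd, frequency = freq,
                  minute_profile = profile,
                  minute_profile_top_devices = profile_top3,
                  floods = floods, flood_summary = fsum),
      avoidable = tech,
      handling = list(episodes = pairing$episodes,
                      duration_summary = dsum),
      sensing = list(pauses = pauses$pauses, pause_metrics = psum,
                     overmonitoring = over),
      exposure = list(room_type = expo, beds_above = above),
      warnings = list(
        rejects = rejects,
        unmatched_events = pairing$unmatched,
        orphan_pause_markers = pauses$orphans,
        empty_log = nrow(entries) == 0
      ),
      provenance = list(
        files = if (is.null(files)) character() else files,
        n_entries = nrow(entries),
        n_by_class = as.list(n_by_class),
        days = length(dates),
        config_hash = rlang::hash(config),
        version = as.character(utils::packageVersion("alarmetrics"))
      )
    ),
    class = "metrics_bundle"
  )
  bundle
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat("<metrics_bundle>\n")
  cat(sprintf("  entries: %d (%d alarm, %d pause, %d other) over %d days\n",
              x$provenance$n_entries, x$provenance$n_by_class$alarm,
              x$provenance$n_by_class$pause, x$provenance$n_by_class$other,
              x$provenance$days))
  cat(sprintf("  alarm load: %.1f (SD %.1f) alarms/bed/day; %d floods (%.2f/day)\n",
              x$load$per_bed_day$mean, x$load$per_bed_day$sd,
              x$load$flood_summary$total, x$load$flood_summary$mean_per_day))
  cat(sprintf("  technical: %d alarms (%.1f/bed/day)\n",
              x$avoidable$total, x$avoidable$per_bed_day_mean))
  med <- x$handling$duration_summary$clinical$median_s
  cat(sprintf("  durations: clinical median %s s, %d outliers (>8 h)\n",
              ifelse(is.na(med), "-", format(med)),
              x$handling$duration_summary$n_outliers))
  pm <- x$sensing$pause_metrics
  cat(sprintf("  pauses: %.2f/bed/day, proper pause-to-pause ratio %.2f:1\n",
              pm$per_bed_day_mean,
              ifelse(is.na(pm$ratio), 0, pm$ratio)))
  cat(sprintf("  exposure: single vs double room %+.0f%%; %.1f beds (%.0f%%) above daily average\n",
              x$exposure$room_type$pct_diff,
              x$exposure$beds_above$mean_beds_above,
              x$exposure$beds_above$pct_beds_above))
  invisible(x)
}

#' Serialise / reload a metrics bundle
#'
#' Writes the bundle as JSON (tables as data frames, timestamps as
#' formatted strings) and reads it back. The reloaded object carries the
#' same values; tibbles come back as data frames.
#'
#' @param bundle A `metrics_bundle`.
#' @param path Output path.
#' @return `write_bundle()`: `path` invisibly; `read_bundle()`: the
#'   bundle list.
#' @export
write_bundle <- function(bundle, path) {
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       POSIXt = "ISO8601", Date = "ISO8601", na = "null",
                       force = TRUE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
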