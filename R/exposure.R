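#' Alarm exposure by room type
#'
#' Compares per-bed alarm frequencies between single- and double-bedroom
#' beds: total alarms per room type divided by the number of beds of
#' that type, both per dataset and per day, overall and per criticality.
#' The percent difference is `(single/double - 1) * 100`.
#'
#' @param events Classified alarm events.
#' @param config A [unit_config()]; supplies the bed-to-room map.
#' @param dates Optional `Date` span (defaults to the span of `events`).
#' @return List: `per_type` tibble (`room_type`, `n_beds`, `total`,
#'   `per_bed`, `per_bed_day`), `per_type_criticality` tibble,
#'   `pct_diff` (overall), `pct_diff_by_criticality` named vector.
#' @export
room_type_exposure <- function(events, config = unit_config(),
                               dates = NULL) {
  gen <- dplyr::filter(events, .data$kind == "generated")
  if (is.null(dates)) dates <- dataset_dates(gen$timestamp)
  n_days <- max(length(dates), 1L)
  bed_type <- config$room_type[config$room_of[config$beds]]
  names(bed_type) <- config$beds
  n_beds_type <- table(bed_type)

  gen <- dplyr::mutate(gen, room_type = unname(bed_type[.data$bed]))
  per_type <- tibble::tibble(room_type = c("single", "double")) |>
    dplyr::left_join(dplyr::count(gen, .data$room_type, name = "total"),
                     by = "room_type") |>
    dplyr::mutate(
      total = tidyr::replace_na(.data$total, 0L),
      n_beds = as.integer(n_beds_type[.data$room_type]),
      per_bed = .data$total / .data$n_beds,
      per_bed_day = .data$per_bed / n_days
    )
  ptc <- tidyr::expand_grid(room_type = c("single", "double"),
                            criticality = c("red", "yellow", "blue")) |>
    dplyr::left_join(
      dplyr::count(gen, .data$room_type, .data$criticality, name = "total"),
      by = c("room_type", "criticality")) |>
    dplyr::mutate(
      total = tidyr::replace_na(.data$total, 0L),
      n_beds = as.integer(n_beds_type[.data$room_type]),
      per_bed = .data$total / .data$n_beds,
      per_bed_day = .data$per_bed / n_days
    )
  pb <- stats::setNames(per_type$per_bed, per_type$room_type)
  diff_crit <- vapply(c("red", "yellow", "blue"), function(cr) {
    x <- ptc[ptc$criticality == cr, ]
    s <- x$per_bed[x$room_type == "single"]
    d <- x$per_bed[x$room_type == "double"]
    if (d > 0) percent_difference(s, d) else NA_real_
  }, numeric(1))
  list(
    per_type = per_type,
    per_type_criticality = ptc,
    pct_diff = if (pb[["double"]] > 0)
      percent_difference(pb[["single"]], pb[["double"]]) else NA_real_,
    pct_diff_by_criticality = diff_crit
  )
}

#' Beds exceeding the unit's daily average
#'
#' For each calendar day: the unit mean alarms per bed, the number of
#' beds strictly above that mean, and the share of the day's alarms
#' those beds issued; then averaged across days. Beds absent from the
#' log on a day contribute zero counts (no occupancy data exists in the
#' log); a variant restricted to beds with at least one alarm that day
#' is emitted alongside.
#'
#' @inheritParams room_type_exposure
#' @return List: `per_day` tibble (`day`, `unit_mean`, `n_above`,
#'   `share_pct`, `n_above_occupied`), `mean_beds_above`,
#'   `sd_beds_above`, `pct_beds_above`, `mean_share_pct`,
#'   `sd_share_pct`, `mean_beds_above_occupied`.
#' @export
beds_above_average <- function(events, config = unit_config(),
                               dates = NULL) {
  gen <- dplyr::filter(events, .data$kind == "generated")
  if (is.null(dates)) dates <- dataset_dates(gen$timestamp)
  beds <- union(config$beds, unique(gen$bed))
  bd <- bed_day_counts(gen, beds, dates)
  per_day <- bd |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      unit_mean = mean(.data$n),
      n_above = sum(.data$n > mean(.data$n)),
      day_total = sum(.data$n),
      share_pct = if (sum(.data$n) > 0)
        percent_share(sum(.data$n[.data$n > mean(.data$n)]), sum(.data$n))
      else NA_real_,
      n_above_occupied = {
        occ <- .data$n[.data$n > 0]
        if (length(occ)) sum(occ > mean(occ)) else 0L
      },
      .groups = "drop"
    )
  list(
    per_day = per_day,
    mean_beds_above = mean(per_day$n_above),
    sd_beds_above = stats::sd(per_day$n_above),
    pct_beds_above = percent_share(mean(per_day$n_above), length(beds)),
    mean_share_pct = mean(per_day$share_pct, na.rm = TRUE),
    sd_share_pct = stats::sd(per_day$share_pct, na.rm = TRUE),
    mean_beds_above_occupied = mean(per_day$n_above_occupied)
  )
}
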