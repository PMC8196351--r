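#' Elementary alarm-metric formulas
#'
#' The scalar definitions behind the alarm-quality dimensions, exposed so
#' that published component counts (totals, bed counts, observation days)
#' can be turned into the derived rates and shares with exactly the same
#' arithmetic the pipeline uses.
#'
#' @param total Total event count.
#' @param beds Number of beds.
#' @param days Number of observation days.
#' @return `rate_per_bed_day()`: events per bed per day.
#' @export
rate_per_bed_day <- function(total, beds, days) {
  total / (beds * days)
}

#' @rdname rate_per_bed_day
#' @param n Numerator count.
#' @param N Denominator count.
#' @return `percent_share()`: `100 * n / N`.
#' @export
percent_share <- function(n, N) 100 * n / N

#' @rdname rate_per_bed_day
#' @param a,b Rates to compare (e.g. single- vs double-room beds).
#' @return `percent_difference()`: `(a / b - 1) * 100`.
#' @export
percent_difference <- function(a, b) (a / b - 1) * 100

#' @rdname rate_per_bed_day
#' @param proper Number of proper pauses.
#' @return `ratio_to_one()`: the proper pause-to-pause ratio `x` in
#'   "x:1" form, i.e. `proper / total`.
#' @export
ratio_to_one <- function(proper, total) proper / total

# calendar dates spanned by an event stream (inclusive); partially
# observed edge days count as full calendar days
dataset_dates <- function(timestamps) {
  if (length(timestamps) == 0) return(as.Date(character()))
  d <- as.Date(timestamps, tz = "UTC")
  seq(min(d), max(d), by = "day")
}

# zero-filled per-(bed, calendar day) counts over a bed set and day span
bed_day_counts <- function(events, beds, dates) {
  grid <- tidyr::expand_grid(bed = beds, day = dates)
  if (nrow(events) == 0) {
    grid$n <- 0L
    return(grid)
  }
  counts <- events |>
    dplyr::mutate(day = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::count(.data$bed, .data$day)
  grid |>
    dplyr::left_join(counts, by = c("bed", "day")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}
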