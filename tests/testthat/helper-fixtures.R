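# Builders and independent oracles shared across the test files.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# minimal classified alarm-event tibble; all columns the metrics consume
mk_events <- function(timestamp, bed, parameter = "HR_LOW",
                      criticality = "red", kind = "generated",
                      is_technical = FALSE, config = unit_config()) {
  tibble::tibble(
    timestamp = ts_utc(timestamp), bed = bed,
    action_raw = NA_character_, device_label = NA_character_,
    class = "alarm",
    criticality = criticality, kind = kind, parameter = parameter,
    device_group = assign_device_group(parameter, config),
    is_technical = is_technical, pause_kind = NA_character_
  )
}

mk_markers <- function(timestamp, bed, pause_kind) {
  tibble::tibble(timestamp = ts_utc(timestamp), bed = bed,
                 pause_kind = pause_kind)
}

# a small unit: 2 single-room + 2 double-room beds
small_unit <- function(...) {
  unit_config(
    beds = c("B1", "B2", "B3", "B4"),
    room_of = c(B1 = "S1", B2 = "S2", B3 = "D1", B4 = "D1"),
    room_type = c(S1 = "single", S2 = "single", D1 = "double"),
    ...
  )
}

# Independent brute-force flood oracle: assigns every event to bin
# floor((t - anchor_bed) / window) by explicit iteration and counts.
brute_force_floods <- function(events, anchors, window_s, threshold) {
  gen <- events[events$kind == "generated", ]
  rows <- list()
  for (b in sort(unique(gen$bed))) {
    ts <- gen$timestamp[gen$bed == b]
    anchor <- if (b %in% names(anchors)) anchors[[b]] else min(ts)
    counts <- new.env()
    for (t in as.numeric(ts)) {
      bin <- as.character(floor((t - as.numeric(anchor)) / window_s))
      counts[[bin]] <- (if (is.null(counts[[bin]])) 0L else counts[[bin]]) + 1L
    }
    for (bin in ls(counts)) {
      if (counts[[bin]] >= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          bed = b, bin = as.numeric(bin), count = counts[[bin]]
        )
      }
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(bed = character(),
                                                bin = numeric(),
                                                count = integer()))))
  out[order(out$bed, out$bin), , drop = FALSE]
}

# random event stream over a few beds; independent of generate_log()
random_stream <- function(n_beds = 5, days = 2, rate_per_day = 120) {
  n <- stats::rpois(1, n_beds * days * rate_per_day)
  mk_events(
    timestamp = ts_utc("2025-03-03 00:00:00") +
      round(stats::runif(n, 0, days * 86400)),
    bed = sample(paste0("B", seq_len(n_beds)), n, replace = TRUE)
  )
}

# flood tibble -> comparable (bed, bin index, count) frame
floods_as_bins <- function(floods, anchors, window_s) {
  bin <- floor((as.numeric(floods$bin_start) -
                  as.numeric(anchors[floods$bed])) / window_s)
  out <- data.frame(bed = floods$bed, bin = bin,
                    count = floods$alarm_count)
  out[order(out$bed, out$bin), , drop = FALSE]
}
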