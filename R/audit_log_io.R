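#' Audit-log dialect
#'
#' The central station exports audit logs as delimited text with four
#' columns: `Time`, `Bedname`, `Action`, `Devicename`. The free-text
#' `Action` column encodes alarm state changes and pause usage; vendors
#' differ in its vocabulary, so the grammar lives here as regex tables
#' and can be adapted to a real export without touching the analysis.
#'
#' The canonical grammar used by the built-in writer and the synthetic
#' generator is:
#' \itemize{
#'   \item alarms: `<CRIT> ALARM <KIND>: <PARAMETER>` with `<CRIT>` one
#'     of `RED`/`YELLOW`/`BLUE` and `<KIND>` `GENERATED`/`TERMINATED`,
#'     e.g. `"RED ALARM GENERATED: ABPs_HIGH"`;
#'   \item pauses: `"ALARM PAUSE STARTED"` / `"ALARM PAUSE ENDED"`.
#' }
#' Anything else (threshold changes, admissions, battery notices outside
#' the alarm grammar) is retained as an `other` entry for audit.
#'
#' @param delimiter Field delimiter, default comma.
#' @param columns Column order of the export.
#' @param ts_format Timestamp format string, default
#'   `"%Y-%m-%d %H:%M:%S"`.
#' @param alarm_pattern Regex with three capture groups: criticality
#'   token, kind token, parameter label.
#' @param criticality_tokens Named character vector mapping criticality
#'   tokens to `red`/`yellow`/`blue`.
#' @param kind_tokens Named character vector mapping kind tokens to
#'   `generated`/`terminated`.
#' @param pause_start_pattern,pause_end_pattern Regexes matching pause
#'   start/end actions.
#' @return A list of class `audit_dialect`.
#' @export
audit_dialect <- function(delimiter = ",",
                          columns = c("Time", "Bedname", "Action",
                                      "Devicename"),
                          ts_format = "%Y-%m-%d %H:%M:%S",
                          alarm_pattern =
                            "^(RED|YELLOW|BLUE) ALARM (GENERATED|TERMINATED): ([A-Za-z0-9_*]+)$",
                          criticality_tokens = c(RED = "red",
                                                 YELLOW = "yellow",
                                                 BLUE = "blue"),
                          kind_tokens = c(GENERATED = "generated",
                                          TERMINATED = "terminated"),
                          pause_start_pattern = "^ALARM PAUSE STARTED$",
                          pause_end_pattern = "^ALARM PAUSE ENDED$") {
  structure(
    list(delimiter = delimiter, columns = columns, ts_format = ts_format,
         alarm_pattern = alarm_pattern,
         criticality_tokens = criticality_tokens,
         kind_tokens = kind_tokens,
         pause_start_pattern = pause_start_pattern,
         pause_end_pattern = pause_end_pattern),
    class = "audit_dialect"
  )
}

.empty_entries <- function() {
  tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    bed_label = character(), action_raw = character(),
    device_label = character()
  )
}

.empty_rejects <- function() {
  tibble::tibble(row = integer(), reason = character(), line = character())
}

#' Parse a clinical audit log
#'
#' Reads a delimited four-column audit-log export into a canonical entry
#' table. Malformed rows (wrong field count, empty field, unparseable
#' timestamp) are never silently dropped: they are collected into a
#' rejects table with the row number and a reason. Entries are sorted
#' stably by timestamp; ties keep file order. Timestamps are interpreted
#' as unit-local clock time and stored timezone-naive (represented in
#' UTC), so daylight-saving transitions appear as 23/25-hour calendar
#' days rather than being re-based.
#'
#' @param file Path to the log file. Exactly one of `file`/`text`.
#' @param text Character vector of log lines (including header).
#' @param dialect An [audit_dialect()].
#' @return A list of class `audit_log` with elements `entries` (tibble:
#'   `timestamp`, `bed_label`, `action_raw`, `device_label`) and
#'   `rejects` (tibble: `row`, `reason`, `line`).
#' @export
parse_audit_log <- function(file = NULL, text = NULL,
                            dialect = audit_dialect()) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- readLines(file, encoding = "UTF-8", warn = FALSE)
  }
  if (length(text) == 0) {
    stop("audit log is empty: expected a header row")
  }
  header <- strsplit(text[[1]], dialect$delimiter, fixed = TRUE)[[1]]
  missing <- setdiff(dialect$columns, trimws(header))
  if (length(missing)) {
    stop("audit log header is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  col_idx <- match(dialect$columns, trimws(header))
  body <- text[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(structure(list(entries = .empty_entries(),
                          rejects = .empty_rejects()),
                     class = "audit_log"))
  }
  fields <- strsplit(body, dialect$delimiter, fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf == length(header)
  reason <- ifelse(ok, NA_character_, "wrong number of fields")

  get_col <- function(nm) {
    i <- col_idx[match(nm, dialect$columns)]
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_,
           character(1))
  }
  time_raw <- get_col("Time")
  bed <- get_col("Bedname")
  action <- get_col("Action")
  device <- get_col("Devicename")

  empty <- ok & (!nzchar(trimws(time_raw)) | !nzchar(trimws(bed)) |
                   !nzchar(trimws(action)) | !nzchar(trimws(device)))
  reason[empty] <- "empty field"
  ok <- ok & !empty

  ts <- as.POSIXct(rep(NA_real_, length(body)), tz = "UTC")
  ts[ok] <- as.POSIXct(time_raw[ok], format = dialect$ts_format, tz = "UTC")
  bad_ts <- ok & is.na(ts)
  reason[bad_ts] <- "unparseable timestamp"
  ok <- ok & !bad_ts

  rejects <- tibble::tibble(
    row = which(!ok) + 1L, # 1-based file row incl. header
    reason = reason[!ok],
    line = body[!ok]
  )
  entries <- tibble::tibble(
    timestamp = ts[ok],
    bed_label = bed[ok],
    action_raw = action[ok],
    device_label = device[ok]
  )
  entries <- entries[order(entries$timestamp), , drop = FALSE]
  structure(list(entries = entries, rejects = rejects), class = "audit_log")
}

#' @export
print.audit_log <- function(x, ...) {
  cat(sprintf("<audit_log> %d entries, %d rejected rows\n",
              nrow(x$entries), nrow(x$rejects)))
  if (nrow(x$entries)) {
    cat(sprintf("  %s .. %s, %d beds\n",
                format(min(x$entries$timestamp)),
                format(max(x$entries$timestamp)),
                length(unique(x$entries$bed_label))))
  }
  invisible(x)
}

#' Write an audit log in the canonical dialect
#'
#' Inverse of [parse_audit_log()]: a parse/write round trip of a valid
#' file reproduces it byte-identically (modulo row sorting).
#'
#' @param entries Entry tibble as returned in `parse_audit_log()$entries`
#'   or by [generate_log()].
#' @param file Output path.
#' @param dialect An [audit_dialect()].
#' @return `file`, invisibly.
#' @export
write_audit_log <- function(entries, file, dialect = audit_dialect()) {
  header <- paste(dialect$columns, collapse = dialect$delimiter)
  cols <- list(
    Time = format(entries$timestamp, dialect$ts_format, tz = "UTC"),
    Bedname = entries$bed_label,
    Action = entries$action_raw,
    Devicename = entries$device_label
  )
  rows <- do.call(paste, c(unname(cols[dialect$columns]),
                           sep = dialect$delimiter))
  writeLines(c(header, rows), file, useBytes = TRUE)
  invisible(file)
}

#' Classify audit-log entries
#'
#' Extracts the alarm variables (criticality, generated/terminated,
#' parameter, device group, technical flag) and the pause markers from
#' the free-text action column. Every entry lands in exactly one class:
#' `alarm`, `pause`, or `other`; unrecognised action texts are `other`,
#' never an error, and stay available for audit.
#'
#' @param entries Entry tibble from [parse_audit_log()].
#' @param config A [unit_config()].
#' @param dialect An [audit_dialect()].
#' @return Tibble with one row per entry: `timestamp`, `bed`,
#'   `action_raw`, `device_label`, `class`, and for alarms `criticality`,
#'   `kind`, `parameter`, `device_group`, `is_technical`; for pauses
#'   `pause_kind`.
#' @export
classify_entries <- function(entries, config = unit_config(),
                             dialect = audit_dialect()) {
  n <- nrow(entries)
  m <- stringr::str_match(entries$action_raw, dialect$alarm_pattern)
  is_alarm <- !is.na(m[, 1])
  is_pstart <- !is_alarm &
    stringr::str_detect(entries$action_raw, dialect$pause_start_pattern)
  is_pend <- !is_alarm & !is_pstart &
    stringr::str_detect(entries$action_raw, dialect$pause_end_pattern)

  cls <- rep("other", n)
  cls[is_alarm] <- "alarm"
  cls[is_pstart | is_pend] <- "pause"

  criticality <- rep(NA_character_, n)
  criticality[is_alarm] <- unname(dialect$criticality_tokens[m[is_alarm, 2]])
  kind <- rep(NA_character_, n)
  kind[is_alarm] <- unname(dialect$kind_tokens[m[is_alarm, 3]])
  parameter <- rep(NA_character_, n)
  parameter[is_alarm] <- m[is_alarm, 4]

  device_group <- rep(NA_character_, n)
  device_group[is_alarm] <- assign_device_group(parameter[is_alarm], config)

  is_technical <- rep(NA, n)
  is_technical[is_alarm] <- criticality[is_alarm] == "blue" |
    parameter[is_alarm] %in% config$technical_parameters

  pause_kind <- rep(NA_character_, n)
  pause_kind[is_pstart] <- "pause_started"
  pause_kind[is_pend] <- "pause_ended"

  tibble::tibble(
    timestamp = entries$timestamp,
    bed = entries$bed_label,
    action_raw = entries$action_raw,
    device_label = entries$device_label,
    class = cls,
    criticality = criticality,
    kind = kind,
    parameter = parameter,
    device_group = device_group,
    is_technical = is_technical,
    pause_kind = pause_kind
  )
}

#' Alarm events / pause markers from a classified entry table
#'
#' @param classified Output of [classify_entries()].
#' @return The alarm (resp. pause-marker) subset.
#' @export
alarm_events <- function(classified) {
  dplyr::filter(classified, .data$class == "alarm")
}

#' @rdname alarm_events
#' @export
pause_markers <- function(classified) {
  dplyr::select(
    dplyr::filter(classified, .data$class == "pause"),
    "timestamp", "bed", "pause_kind"
  )
}

#' Deidentify an audit log
#'
#' Shifts all dates into the future by a whole number of weeks and
#' replaces bed labels with pseudonyms. Restricting the offset to
#' multiples of 7 days makes weekday structure provably invariant:
#' time-of-day, weekday and all inter-event intervals are preserved
#' exactly.
#'
#' @param entries Entry tibble from [parse_audit_log()].
#' @param day_offset Non-negative day offset, must be a multiple of 7.
#' @param bed_pseudonyms Named character vector mapping every observed
#'   bed label to a pseudonym; must be injective.
#' @return Entry tibble with shifted timestamps and pseudonymous beds.
#' @export
deidentify_log <- function(entries, day_offset, bed_pseudonyms) {
  stopifnot(day_offset >= 0, day_offset %% 7 == 0)
  observed <- unique(entries$bed_label)
  missing <- setdiff(observed, names(bed_pseudonyms))
  if (length(missing)) {
    stop("no pseudonym for bed(s): ", paste(missing, collapse = ", "))
  }
  used <- bed_pseudonyms[observed]
  if (anyDuplicated(used)) {
    stop("bed pseudonym map is not injective over observed beds")
  }
  entries$timestamp <- entries$timestamp + day_offset * 86400
  entries$bed_label <- unname(bed_pseudonyms[entries$bed_label])
  entries
}
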