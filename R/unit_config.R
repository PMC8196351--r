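#' Default parameter-to-device map
#'
#' Maps canonical alarm-parameter labels to one of the seven monitored
#' device groups (ventilator, ECG, IBP, ICP, temperature, NIBP, SpO2).
#' Parameters absent from the map fall into the `other` bucket, which is
#' retained in all totals.
#'
#' @return Named character vector, names are parameter labels and values
#'   device groups.
#' @export
default_device_map <- function() {
  c(
    # ventilator
    VENT_GENERIC = "ventilator", FREQUENCY = "ventilator",
    APNEA_VENT = "ventilator", MV_LOW = "ventilator",
    PEEP_HIGH = "ventilator",
    # ECG
    HR_LOW = "ECG", HR_HIGH = "ECG", RR_HIGH = "ECG",
    APNEA_ECG = "ECG", ECG_LEAD_OFF = "ECG", ASYSTOLE = "ECG",
    # invasive blood pressure
    ABPs_HIGH = "IBP", ABPs_LOW = "IBP", ABPm_LOW = "IBP",
    ART_INTERRUPTED = "IBP",
    # intracranial pressure
    ICP_HIGH = "ICP",
    # temperature
    TEMP_HIGH = "temperature", TEMP_LOW = "temperature",
    # non-invasive blood pressure
    NIBP_HIGH = "NIBP", NIBP_LOW = "NIBP",
    # pulse oximetry
    SPO2_LOW = "SpO2", SPO2_SENSOR = "SpO2"
  )
}

#' Device groups recognised by the analysis
#' @return Character vector of the seven device groups plus `other`.
#' @export
device_groups <- function() {
  c("ventilator", "ECG", "IBP", "ICP", "temperature", "NIBP", "SpO2", "other")
}

.default_beds <- function() sprintf("ICU-%02d", 1:21)

.default_rooms <- function(beds = .default_beds()) {
  # 9 single rooms (one bed each) + 6 double rooms (two beds each)
  # = 21 beds in 15 rooms, 9 single-room beds and 12 double-room beds.
  room_of <- c(
    stats::setNames(sprintf("R%02d", 1:9), beds[1:9]),
    stats::setNames(rep(sprintf("R%02d", 10:15), each = 2), beds[10:21])
  )
  room_type <- c(
    stats::setNames(rep("single", 9), sprintf("R%02d", 1:9)),
    stats::setNames(rep("double", 6), sprintf("R%02d", 10:15))
  )
  list(room_of = room_of, room_type = room_type)
}

#' Default nursing shift table
#'
#' Three 8-hour shifts; the first `handover_min` minutes of each shift are
#' treated as the handover period and excluded from per-shift statistics.
#'
#' @return Tibble with columns `shift`, `start_min`, `end_min`,
#'   `handover_min` (minutes of day; the night shift wraps midnight).
#' @export
default_shifts <- function() {
  tibble::tibble(
    shift = c("morning", "afternoon", "night"),
    start_min = c(6L, 14L, 22L) * 60L,
    end_min = c(14L, 22L, 30L) * 60L, # night ends 06:00 next day
    handover_min = 30L
  )
}

#' Unit configuration
#'
#' Describes the monitored unit and the analysis constants: bed and room
#' layout, shift times, alarm-flood definition, pause semantics, the
#' duration-outlier cutoff, the parameter-to-device map and the technical
#' parameter set.
#'
#' Defaults describe a 21-bed unit with 15 rooms (9 single-room beds, 12
#' double-room beds), an alarm flood of >= 10 alarms within a 10-minute
#' bin, a 3-minute monitor pause with a 3-minute re-enable merge gap, an
#' 8-hour alarm-duration outlier cutoff, and a 500-alarm minimum for a
#' device group to be reported individually.
#'
#' @param beds Character vector of bed identifiers.
#' @param room_of Named character vector bed -> room.
#' @param room_type Named character vector room -> "single"/"double".
#' @param shifts Shift table, see [default_shifts()].
#' @param flood_window_s Flood bin width in seconds.
#' @param flood_threshold Minimum alarms per bin to count as a flood.
#' @param pause_default_s Monitor default alarm-pause length in seconds.
#' @param pause_merge_gap_s Pauses re-enabled within this many seconds of
#'   a previous pause's end are merged into one continuous pause.
#' @param duration_outlier_s Alarm durations above this are outliers.
#' @param min_device_count Device groups with fewer total alarms are only
#'   included in overall counts, not reported individually.
#' @param device_map Named character vector parameter -> device group.
#' @param technical_parameters Parameters counted as technical alarms
#'   regardless of criticality (blue-criticality alarms are always
#'   technical).
#' @param rr_parameters Named character vector of respiratory-rate-type
#'   parameters, values are the issuing device group.
#' @param apnea_parameters Named character vector of apnea-type
#'   parameters, values are the issuing device group.
#' @param pairing Alarm pairing discipline, `"fifo"` (default) or
#'   `"lifo"`.
#' @return A list of class `unit_config`.
#' @export
unit_config <- function(beds = .default_beds(),
                        room_of = NULL,
                        room_type = NULL,
                        shifts = default_shifts(),
                        flood_window_s = 600,
                        flood_threshold = 10,
                        pause_default_s = 180,
                        pause_merge_gap_s = 180,
                        duration_outlier_s = 28800,
                        min_device_count = 500,
                        device_map = default_device_map(),
                        technical_parameters = c(
                          "ART_INTERRUPTED", "ECG_LEAD_OFF", "SPO2_SENSOR",
                          "MODULE_CABLE", "BATTERY_LOW", "MISSING_PATIENT_INFO"
                        ),
                        rr_parameters = c(RR_HIGH = "ECG",
                                          FREQUENCY = "ventilator"),
                        apnea_parameters = c(APNEA_ECG = "ECG",
                                             APNEA_VENT = "ventilator"),
                        pairing = c("fifo", "lifo")) {
  if (is.null(room_of) || is.null(room_type)) {
    stopifnot(identical(beds, .default_beds()))
    rooms <- .default_rooms(beds)
    room_of <- rooms$room_of
    room_type <- rooms$room_type
  }
  pairing <- match.arg(pairing)
  stopifnot(
    flood_threshold >= 1,
    flood_window_s > 0, pause_default_s > 0, pause_merge_gap_s > 0,
    duration_outlier_s > 0,
    all(beds %in% names(room_of)),
    all(room_of[beds] %in% names(room_type)),
    all(room_type %in% c("single", "double"))
  )
  structure(
    list(
      beds = beds, room_of = room_of, room_type = room_type,
      shifts = shifts,
      flood_window_s = flood_window_s, flood_threshold = flood_threshold,
      pause_default_s = pause_default_s,
      pause_merge_gap_s = pause_merge_gap_s,
      duration_outlier_s = duration_outlier_s,
      min_device_count = min_device_count,
      device_map = device_map,
      technical_parameters = technical_parameters,
      rr_parameters = rr_parameters,
      apnea_parameters = apnea_parameters,
      pairing = pairing
    ),
    class = "unit_config"
  )
}

#' @export
print.unit_config <- function(x, ...) {
  n_single <- sum(x$room_type[x$room_of[x$beds]] == "single")
  cat("<unit_config>\n")
  cat(sprintf("  %d beds in %d rooms (%d single-room, %d double-room beds)\n",
              length(x$beds), length(unique(x$room_of[x$beds])),
              n_single, length(x$beds) - n_single))
  cat(sprintf("  flood: >=%d alarms / %ds bin; pause default %ds, merge gap %ds\n",
              x$flood_threshold, x$flood_window_s,
              x$pause_default_s, x$pause_merge_gap_s))
  cat(sprintf("  duration outlier cutoff %ds; device map: %d parameters\n",
              x$duration_outlier_s, length(x$device_map)))
  invisible(x)
}

#' Map alarm parameters to device groups
#'
#' Parameters not present in the configured device map are assigned to
#' `other`; such alarms still count towards all overall totals.
#'
#' @param parameter Character vector of parameter labels.
#' @param config A [unit_config()].
#' @return Character vector of device groups.
#' @export
assign_device_group <- function(parameter, config = unit_config()) {
  grp <- unname(config$device_map[parameter])
  grp[is.na(grp)] <- "other"
  grp
}

# shift label for each minute-of-day (0..1439); NA never occurs with the
# default table because the three shifts tile the day
shift_of_minute <- function(minute, shifts = default_shifts()) {
  out <- rep(NA_character_, length(minute))
  for (i in seq_len(nrow(shifts))) {
    s <- shifts$start_min[i]
    e <- shifts$end_min[i]
    hit <- if (e > 1440L) minute >= s | minute < (e - 1440L) else
      minute >= s & minute < e
    out[hit] <- shifts$shift[i]
  }
  out
}

# TRUE for minutes inside a handover window (first handover_min minutes
# of each shift), which per-shift statistics exclude
in_handover <- function(minute, shifts = default_shifts()) {
  hit <- rep(FALSE, length(minute))
  for (i in seq_len(nrow(shifts))) {
    s <- shifts$start_min[i]
    h <- shifts$handover_min[i]
    hit <- hit | (minute >= s & minute < s + h)
  }
  hit
}
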