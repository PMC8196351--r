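#' Read a unit/dialect configuration file
#'
#' Loads a single declarative YAML file holding the unit description and
#' the audit-log dialect, e.g.:
#'
#' ```yaml
#' unit:
#'   flood_threshold: 10
#'   beds: [B1, B2, B3]
#'   room_of: {B1: R1, B2: R2, B3: R2}
#'   room_type: {R1: single, R2: double}
#'   device_map: {HR_LOW: ECG, ABPs_HIGH: IBP}
#' dialect:
#'   delimiter: ";"
#'   ts_format: "%d.%m.%Y %H:%M:%S"
#' ```
#'
#' Any field accepted by [unit_config()] / [audit_dialect()] may appear;
#' omitted fields keep their defaults. `shifts` may be given as a list of
#' records with the [default_shifts()] columns.
#'
#' @param path Path to the YAML file.
#' @return List with elements `unit` (a `unit_config`) and `dialect` (an
#'   `audit_dialect`).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_named_chr <- function(x) {
    if (is.null(x)) NULL else unlist(x)
  }
  u <- raw$unit
  if (!is.null(u)) {
    for (f in c("room_of", "room_type", "device_map", "rr_parameters",
                "apnea_parameters")) {
      if (!is.null(u[[f]])) u[[f]] <- as_named_chr(u[[f]])
    }
    for (f in c("beds", "technical_parameters")) {
      if (!is.null(u[[f]])) u[[f]] <- as.character(unlist(u[[f]]))
    }
    if (!is.null(u$shifts)) {
      u$shifts <- dplyr::bind_rows(lapply(u$shifts, tibble::as_tibble))
    }
  }
  d <- raw$dialect
  if (!is.null(d)) {
    for (f in c("criticality_tokens", "kind_tokens")) {
      if (!is.null(d[[f]])) d[[f]] <- as_named_chr(d[[f]])
    }
    if (!is.null(d$columns)) d$columns <- as.character(unlist(d$columns))
  }
  list(
    unit = do.call(unit_config, if (is.null(u)) list() else u),
    dialect = do.call(audit_dialect, if (is.null(d)) list() else d)
  )
}
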