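# Field measurement tables: long-format records of per-plant, per-organ
# parameter measurements, the raw material for fitting a parameter database.

MEASUREMENT_COLUMNS <- c("plant_id", "organ_class", "instance_id",
                         "parameter", "value", "units")

#' Validate a measurement table
#'
#' A measurement table is a data frame with columns \code{plant_id},
#' \code{organ_class}, \code{instance_id}, \code{parameter}, \code{value}
#' and \code{units} (one row per measured value). Units must be consistent
#' per parameter (deg, mm or count) and values finite.
#'
#' @param table A data frame.
#' @return The table, invisibly.
#' @export
validate_measurements <- function(table) {
  if (!is.data.frame(table))
    stop("measurement table must be a data frame", call. = FALSE)
  miss <- setdiff(MEASUREMENT_COLUMNS, names(table))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(table)) {
    if (any(!is.finite(table$value)))
      stop("measurement table contains non-finite values", call. = FALSE)
    bad <- !table$organ_class %in% ORGAN_CLASSES
    if (any(bad))
      stop("unknown organ class in measurements: ",
           paste(unique(table$organ_class[bad]), collapse = ", "),
           call. = FALSE)
    expect <- parameter_units(table$parameter)
    if (any(table$units != expect))
      stop("inconsistent units for parameter(s): ",
           paste(unique(table$parameter[table$units != expect]),
                 collapse = ", "), call. = FALSE)
  }
  invisible(table)
}

#' Read / write measurement tables as CSV
#'
#' Plain CSV with header
#' \code{plant_id,organ_class,instance_id,parameter,value,units}.
#'
#' @param table A measurement table data frame.
#' @param path CSV file path.
#' @return \code{write_measurements} returns \code{path} invisibly;
#'   \code{read_measurements} returns the validated table.
#' @export
write_measurements <- function(table, path) {
  validate_measurements(table)
  utils::write.csv(table[, MEASUREMENT_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(tab)
  tab
}
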