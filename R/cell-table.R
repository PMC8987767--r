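# Cell feature tables: one row per measured cell with the four features the
# flowchart consumes. The canonical schema is
#   cell_id             character, unique
#   diameter_um         double > 0
#   cornification_lines integer >= 0
#   nucleus_area_um2    double >= 0, NA iff nucleus_state == "absent"
#   nucleus_state       one of "absent", "eroded", "demarcated"

#' Build a cell feature table
#'
#' Assembles and validates a tibble of per-cell morphometric features, the
#' common currency of the package: the classifier, the calibration routines
#' and the synthetic generator all speak this schema.
#'
#' @param cell_id Character vector of unique cell identifiers. Defaults to
#'   `"cell_1"`, `"cell_2"`, ...
#' @param diameter_um Cell diameter (maximum caliper) in µm, strictly positive.
#' @param cornification_lines Non-negative integer count of cornification
#'   lines (angular folds) visible on the cell.
#' @param nucleus_area_um2 Nucleus area in µm²; `NA` exactly when
#'   `nucleus_state` is `"absent"`.
#' @param nucleus_state One of `"absent"`, `"eroded"`, `"demarcated"`
#'   (case-insensitive).
#' @return A validated tibble with the canonical columns.
#' @examples
#' cell_table(diameter_um = c(15, 42), cornification_lines = c(0L, 3L),
#'            nucleus_area_um2 = c(55, NA),
#'            nucleus_state = c("demarcated", "absent"))
#' @export
cell_table <- function(diameter_um,
                       cornification_lines,
                       nucleus_area_um2,
                       nucleus_state,
                       cell_id = paste0("cell_", seq_along(diameter_um))) {
  out <- tibble(
    cell_id = as.character(cell_id),
    diameter_um = as.double(diameter_um),
    cornification_lines = vctrs_int(cornification_lines),
    nucleus_area_um2 = as.double(nucleus_area_um2),
    nucleus_state = tolower(as.character(nucleus_state))
  )
  validate_cell_table(out)
}

vctrs_int <- function(x) {
  if (is.double(x) && any(!is.na(x) & x != round(x))) {
    abort("`cornification_lines` must be whole numbers.",
          class = "cytovag_error_validation")
  }
  as.integer(x)
}

#' Validate a cell feature table
#'
#' Checks the schema invariants and returns the table invisibly unchanged
#' (extra columns such as `true_class` are tolerated and passed through).
#' Violations raise a classed error naming the offending field.
#'
#' @param cells A data frame with the canonical cell-table columns.
#' @return The input as a tibble, invisibly validated.
#' @export
validate_cell_table <- function(cells) {
  required <- c("cell_id", "diameter_um", "cornification_lines",
                "nucleus_area_um2", "nucleus_state")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    abort(paste0("Cell table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "cytovag_error_validation")
  }
  cells <- as_tibble(cells)
  cells$nucleus_state <- tolower(as.character(cells$nucleus_state))

  bad_state <- !cells$nucleus_state %in% NUCLEUS_STATES
  if (any(bad_state)) {
    abort(paste0("`nucleus_state` contains invalid value(s): ",
                 paste(unique(cells$nucleus_state[bad_state]), collapse = ", "),
                 " (allowed: ", paste(NUCLEUS_STATES, collapse = ", "), ")."),
          class = "cytovag_error_validation")
  }
  if (any(is.na(cells$diameter_um)) || any(cells$diameter_um <= 0)) {
    abort("`diameter_um` must be strictly positive for every cell.",
          class = "cytovag_error_validation")
  }
  if (any(is.na(cells$cornification_lines)) ||
      any(cells$cornification_lines < 0)) {
    abort("`cornification_lines` must be a non-negative integer count.",
          class = "cytovag_error_validation")
  }
  absent <- cells$nucleus_state == "absent"
  if (any(absent & !is.na(cells$nucleus_area_um2))) {
    abort(paste0("`nucleus_area_um2` must be absent (NA) when ",
                 "`nucleus_state` is \"absent\"."),
          class = "cytovag_error_validation")
  }
  if (any(!absent & is.na(cells$nucleus_area_um2))) {
    abort(paste0("`nucleus_area_um2` is missing for cells whose ",
                 "`nucleus_state` is not \"absent\"."),
          class = "cytovag_error_validation")
  }
  if (any(!absent & cells$nucleus_area_um2 < 0, na.rm = TRUE)) {
    abort("`nucleus_area_um2` must be non-negative.",
          class = "cytovag_error_validation")
  }
  if (anyDuplicated(cells$cell_id) > 0) {
    abort("`cell_id` values must be unique.",
          class = "cytovag_error_validation")
  }
  cells
}

#' Read a cell feature table from CSV
#'
#' Strict reader for the canonical cell-table CSV schema. An empty
#' `nucleus_area_um2` field encodes an absent nucleus; literal `"NaN"`,
#' `"NA"` or `"null"` entries are rejected so that a true measurement of 0
#' µm² can never be confused with absence.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated cell-table tibble (extra columns retained).
#' @export
read_cell_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  required <- c("cell_id", "diameter_um", "cornification_lines",
                "nucleus_area_um2", "nucleus_state")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("CSV is missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "cytovag_error_validation")
  }
  bad_literals <- c("nan", "na", "null", "none")
  if (any(tolower(raw$nucleus_area_um2) %in% bad_literals)) {
    abort(paste0("`nucleus_area_um2` must be a number or an empty field ",
                 "(absent nucleus); literals like \"NaN\"/\"null\" are not ",
                 "accepted."),
          class = "cytovag_error_validation")
  }
  out <- raw
  out$diameter_um <- parse_strict_double(raw$diameter_um, "diameter_um")
  out$cornification_lines <-
    parse_strict_int(raw$cornification_lines, "cornification_lines")
  area <- rep(NA_real_, nrow(raw))
  filled <- raw$nucleus_area_um2 != ""
  area[filled] <- parse_strict_double(raw$nucleus_area_um2[filled],
                                      "nucleus_area_um2")
  out$nucleus_area_um2 <- area
  validate_cell_table(out)
}

parse_strict_double <- function(x, field) {
  val <- suppressWarnings(as.double(x))
  if (any(is.na(val) | x == "")) {
    abort(paste0("Column `", field, "` contains non-numeric or empty ",
                 "value(s)."),
          class = "cytovag_error_validation")
  }
  val
}

parse_strict_int <- function(x, field) {
  val <- parse_strict_double(x, field)
  if (any(val != round(val))) {
    abort(paste0("Column `", field, "` must contain whole numbers."),
          class = "cytovag_error_validation")
  }
  as.integer(val)
}

#' Write a cell feature table to CSV
#'
#' Absent nucleus areas are written as empty fields (never `"NA"`), so a
#' [read_cell_table()] round trip is lossless.
#'
#' @param cells A validated cell-table tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  cells <- validate_cell_table(cells)
  readr::write_csv(cells, path, na = "", progress = FALSE)
  invisible(path)
}
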