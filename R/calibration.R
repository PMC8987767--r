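# Data-driven threshold derivation. The intermediate/superficial nucleus
# area cut-off is the 95th percentile of nucleus areas measured on cornified
# cells with a demarcated nucleus; the parabasal 20 um rule is validated by
# checking that small cells show neither cornification nor nuclear change.

#' Percentile-based nucleus-area threshold
#'
#' Derives a classification threshold as the q-th percentile of a sample of
#' nucleus areas, the procedure behind the 79.5 µm² intermediate-cell
#' cut-off: measure nuclei of cornified cells with a demarcated nucleus
#' (superficial cells), take the 95th percentile, and classify nuclei at or
#' above it as intermediate. Percentiles use linear interpolation between
#' closest ranks (R's default quantile type 7) unless another `type` is
#' given.
#'
#' @param areas Numeric vector of nucleus areas in µm² (at least two finite,
#'   non-negative values), or a cell feature table from which areas of
#'   cornified, demarcated-nucleus cells are extracted (cells with at least
#'   `cornified_min_lines` cornification lines and a demarcated nucleus).
#' @param q Percentile in (0, 100); default 95.
#' @param type Quantile estimator type passed to [stats::quantile()]
#'   (default 7).
#' @param config A [classifier_config()]; only used to select cells when
#'   `areas` is a cell table.
#' @return An object of class `cyto_calibration` with `sample_size`,
#'   `mean_area`, `sd_area` (sample SD, n-1 denominator), `percentile_q`,
#'   `threshold` and the raw `areas`. [glance()] returns the one-row summary;
#'   [autoplot()] draws the area histogram with the threshold marked.
#' @examples
#' set.seed(1)
#' percentile_threshold(rnorm(500, 57.7, 13.8))
#' @export
percentile_threshold <- function(areas, q = 95, type = 7,
                                 config = classifier_config()) {
  if (is.data.frame(areas)) {
    cells <- validate_cell_table(areas)
    keep <- cells$cornification_lines >= config$cornified_min_lines &
      cells$nucleus_state == "demarcated"
    areas <- cells$nucleus_area_um2[keep]
  }
  if (!is.numeric(areas) || length(areas) < 2) {
    abort("At least two area values are required for calibration.",
          class = "cytovag_error_validation")
  }
  if (any(!is.finite(areas))) {
    abort("`areas` must be finite (no NA/NaN/Inf).",
          class = "cytovag_error_validation")
  }
  if (any(areas < 0)) {
    abort("`areas` must be non-negative.",
          class = "cytovag_error_validation")
  }
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 100) {
    abort("`q` must be a single percentage strictly between 0 and 100.",
          class = "cytovag_error_validation")
  }
  threshold <- unname(quantile(areas, probs = q / 100, type = type))
  structure(
    list(sample_size = length(areas),
         mean_area = mean(areas),
         sd_area = sd(areas),
         percentile_q = q,
         threshold = threshold,
         areas = as.numeric(areas)),
    class = "cyto_calibration"
  )
}

#' @export
print.cyto_calibration <- function(x, ...) {
  cat("<cyto_calibration>\n")
  cat(sprintf("  n = %d nuclei, mean %.1f um2 (SD %.1f um2)\n",
              x$sample_size, x$mean_area, x$sd_area))
  cat(sprintf("  %g-th percentile threshold: %.1f um2\n",
              x$percentile_q, x$threshold))
  invisible(x)
}

#' @rdname percentile_threshold
#' @param x A `cyto_calibration` object.
#' @param ... Unused.
#' @method glance cyto_calibration
#' @export
glance.cyto_calibration <- function(x, ...) {
  tibble(sample_size = x$sample_size, mean_area = x$mean_area,
         sd_area = x$sd_area, percentile_q = x$percentile_q,
         threshold = x$threshold)
}

#' Validate the parabasal small-cell rule
#'
#' The diameter rule assumes every epithelial cell below the parabasal
#' maximum diameter is an unaltered parabasal cell. This check measures how
#' often that assumption fails in a sample: among cells with
#' `diameter_um < max_diameter`, it reports the count and fraction showing
#' any cornification line or a nucleus that is not demarcated. The rule
#' holds when that fraction is exactly zero, mirroring the validation on 200
#' measured small cells in which not one cell showed cornification or
#' nuclear change.
#'
#' @param cells A cell feature table.
#' @param max_diameter Diameter cut-off in µm (default 20); cells strictly
#'   below it are evaluated.
#' @return A one-row tibble with `n_cells`, `n_evaluable`, `n_violations`,
#'   `violation_fraction`, `rule_holds` and `evaluable` (FALSE when no cell
#'   lies below the cut-off, in which case the fractions are `NA` rather
#'   than an error).
#' @export
validate_parabasal_rule <- function(cells, max_diameter = 20.0) {
  cells <- validate_cell_table(cells)
  if (nrow(cells) == 0) {
    abort("`cells` must contain at least one record.",
          class = "cytovag_error_empty")
  }
  small <- cells$diameter_um < max_diameter
  if (!any(small)) {
    return(tibble(n_cells = nrow(cells), n_evaluable = 0L,
                  n_violations = NA_integer_,
                  violation_fraction = NA_real_,
                  rule_holds = NA, evaluable = FALSE))
  }
  sub <- cells[small, ]
  violating <- sub$cornification_lines >= 1 |
    sub$nucleus_state != "demarcated"
  tibble(n_cells = nrow(cells),
         n_evaluable = sum(small),
         n_violations = sum(violating),
         violation_fraction = mean(violating),
         rule_holds = !any(violating),
         evaluable = TRUE)
}
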