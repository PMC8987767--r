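# Estrous cycle staging from smear composition. The literature offers
# several non-equivalent percentage criteria for cytological estrus; all are
# exposed as selectable rule sets and none is declared canonical. The
# diestrus-onset rule combines a drop in cornified-cell proportion with the
# appearance of neutrophils.

ESTRUS_RULE_SETS <- c("antonov", "feldman90", "kustritz")

#' Assemble a smear profile directly from summary fractions
#'
#' Convenience constructor for a `cyto_smear_profile` when only the
#' composition summary is known (e.g. from a published table) rather than
#' per-cell records. See [smear_profile()] for computing a profile from a
#' cell table.
#'
#' @param proportions Named numeric vector over [CELL_CLASSES] (missing
#'   classes default to 0); must sum to 1.
#' @param n_cells Number of cells behind the proportions.
#' @param pyknotic_or_absent_fraction,anuclear_fraction,cornified_fraction
#'   Fractions in `[0, 1]`; defaults 0.
#' @param neutrophils_present Logical.
#' @param neutrophil_count Optional count (defaults to 0 or, if
#'   `neutrophils_present`, `NA`).
#' @return A `cyto_smear_profile`.
#' @export
as_smear_profile <- function(proportions, n_cells = 100L,
                             pyknotic_or_absent_fraction = 0,
                             anuclear_fraction = 0,
                             cornified_fraction = 0,
                             neutrophils_present = FALSE,
                             neutrophil_count = NULL) {
  props <- setNames(rep(0, length(CELL_CLASSES)), CELL_CLASSES)
  unknown <- setdiff(names(proportions), CELL_CLASSES)
  if (length(unknown) > 0) {
    abort(paste0("Unknown cell class(es) in `proportions`: ",
                 paste(unknown, collapse = ", "), "."),
          class = "cytovag_error_validation")
  }
  props[names(proportions)] <- proportions
  if (any(props < 0) || abs(sum(props) - 1) > 1e-9) {
    abort("`proportions` must be non-negative and sum to 1.",
          class = "cytovag_error_validation")
  }
  fracs <- c(pyknotic_or_absent_fraction, anuclear_fraction,
             cornified_fraction)
  if (any(fracs < 0) || any(fracs > 1)) {
    abort("Fractions must lie in [0, 1].",
          class = "cytovag_error_validation")
  }
  structure(
    list(counts = setNames(as.integer(round(props * n_cells)), CELL_CLASSES),
         proportions = props,
         n_cells = as.integer(n_cells),
         pyknotic_or_absent_fraction = pyknotic_or_absent_fraction,
         anuclear_fraction = anuclear_fraction,
         cornified_fraction = cornified_fraction,
         neutrophil_count = neutrophil_count %||%
           (if (neutrophils_present) NA_integer_ else 0L),
         neutrophils_present = isTRUE(neutrophils_present)),
    class = "cyto_smear_profile"
  )
}

new_stage_call <- function(stage, rule_set, criteria) {
  stopifnot(nrow(criteria) >= 1)
  structure(list(stage = stage, rule_set = rule_set, criteria = criteria),
            class = "cyto_stage_call")
}

criterion_row <- function(criterion, observed, threshold, pass) {
  tibble(criterion = criterion, observed = observed, threshold = threshold,
         pass = pass)
}

#' Call cytological estrus from a smear profile
#'
#' Evaluates one of three literature rule sets against a smear composition,
#' with the printed inequalities applied strictly:
#'
#' * `"antonov"`: 100 % superficial (incl. anuclear squamous) cells *and*
#'   more than 80 % of cells with a pyknotic or absent nucleus.
#' * `"feldman90"`: more than 90 % superficial keratinized epithelial cells
#'   (superficial plus squamous).
#' * `"kustritz"`: 100 % cornification *and* more than 50 % anuclear
#'   squames.
#'
#' @param profile A `cyto_smear_profile` (from [smear_profile()] or
#'   [as_smear_profile()]).
#' @param rule_set One of `"antonov"`, `"feldman90"`, `"kustritz"`.
#' @return A `cyto_stage_call` with `stage` `"estrus_positive"` or
#'   `"estrus_negative"`, the rule set used, and a `criteria` tibble giving
#'   each criterion's observed value, threshold and pass flag.
#' @examples
#' p <- as_smear_profile(c(superficial = 0.4, squamous = 0.6),
#'                       pyknotic_or_absent_fraction = 0.85,
#'                       anuclear_fraction = 0.6, cornified_fraction = 1)
#' call_estrus(p, "antonov")
#' @export
call_estrus <- function(profile, rule_set = c("antonov", "feldman90",
                                              "kustritz")) {
  stopifnot(inherits(profile, "cyto_smear_profile"))
  if (profile$n_cells < 1) {
    abort("Profile must be based on at least one cell.",
          class = "cytovag_error_validation")
  }
  if (!is.character(rule_set) || !rule_set[1] %in% ESTRUS_RULE_SETS) {
    abort(paste0("Unknown rule set; valid options: ",
                 paste(ESTRUS_RULE_SETS, collapse = ", "), "."),
          class = "cytovag_error_validation")
  }
  rule_set <- rule_set[1]
  sup_sq <- profile$proportions[["superficial"]] +
    profile$proportions[["squamous"]]
  eps <- 1e-9

  criteria <- switch(rule_set,
    antonov = bind_rows(
      criterion_row("superficial + squamous proportion = 100%",
                    sup_sq, 1, sup_sq >= 1 - eps),
      criterion_row("pyknotic or absent nuclei > 80%",
                    profile$pyknotic_or_absent_fraction, 0.80,
                    profile$pyknotic_or_absent_fraction > 0.80)),
    feldman90 = criterion_row(
      "superficial keratinized cells > 90%",
      sup_sq, 0.90, sup_sq > 0.90),
    kustritz = bind_rows(
      criterion_row("cornified fraction = 100%",
                    profile$cornified_fraction, 1,
                    profile$cornified_fraction >= 1 - eps),
      criterion_row("anuclear squames > 50%",
                    profile$anuclear_fraction, 0.50,
                    profile$anuclear_fraction > 0.50)))

  stage <- if (all(criteria$pass)) "estrus_positive" else "estrus_negative"
  new_stage_call(stage, rule_set, criteria)
}

#' Call the onset of diestrus from two consecutive smears
#'
#' The onset of diestrus is called when the superficial-plus-squamous
#' proportion has decreased by at least 20 percentage points relative to the
#' previous smear *and* neutrophil granulocytes are present in the current
#' smear. With `relative = TRUE` the drop is measured as a relative decline
#' (current at most 80 % of the previous proportion) instead of an absolute
#' percentage-point difference.
#'
#' @param current,previous `cyto_smear_profile`s of the current and the
#'   preceding smear.
#' @param drop Minimum decrease (default 0.20).
#' @param relative Interpret `drop` as a relative decline (default `FALSE`:
#'   absolute percentage points).
#' @return A `cyto_stage_call` with stage `"diestrus_onset"` or
#'   `"indeterminate"`.
#' @export
call_diestrus_onset <- function(current, previous, drop = 0.20,
                                relative = FALSE) {
  stopifnot(inherits(current, "cyto_smear_profile"),
            inherits(previous, "cyto_smear_profile"))
  cur <- current$proportions[["superficial"]] +
    current$proportions[["squamous"]]
  prev <- previous$proportions[["superficial"]] +
    previous$proportions[["squamous"]]
  observed_drop <- if (relative) {
    if (prev > 0) (prev - cur) / prev else 0
  } else {
    prev - cur
  }
  criteria <- bind_rows(
    criterion_row(
      if (relative) {
        "superficial + squamous relative decline >= 20%"
      } else {
        "superficial + squamous decreased by >= 20 percentage points"
      },
      observed_drop, drop, observed_drop >= drop - 1e-12),
    criterion_row("neutrophil granulocytes present",
                  as.numeric(current$neutrophils_present), 1,
                  isTRUE(current$neutrophils_present)))
  stage <- if (all(criteria$pass)) "diestrus_onset" else "indeterminate"
  new_stage_call(stage, "diestrus_onset", criteria)
}

#' @export
print.cyto_stage_call <- function(x, ...) {
  cat("<cyto_stage_call>", x$stage, "(rule set:", paste0(x$rule_set, ")"),
      "\n")
  for (i in seq_len(nrow(x$criteria))) {
    cat(sprintf("  [%s] %s (observed %.3f, threshold %.2f)\n",
                if (x$criteria$pass[i]) "pass" else "fail",
                x$criteria$criterion[i], x$criteria$observed[i],
                x$criteria$threshold[i]))
  }
  invisible(x)
}

#' @rdname call_estrus
#' @param x A `cyto_stage_call`.
#' @param ... Unused.
#' @method tidy cyto_stage_call
#' @export
tidy.cyto_stage_call <- function(x, ...) {
  x$criteria
}

#' @rdname call_estrus
#' @method glance cyto_stage_call
#' @export
glance.cyto_stage_call <- function(x, ...) {
  tibble(stage = x$stage, rule_set = x$rule_set,
         n_criteria = nrow(x$criteria), all_pass = all(x$criteria$pass))
}
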