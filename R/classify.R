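# The flowchart classifier. Decision order:
#   Step 1  diameter: <= 20 um -> parabasal, else continue
#   Step 2  cornification grade: < 2 lines = "none or slight" -> Step 2a;
#           >= 2 lines = "moderate to significant" -> Step 3a
#   Step 2a nuclear area: >= 79.5 um^2 -> intermediate, else Step 3a
#   Step 3a nucleus visibility: absent -> squamous, else Step 3b
#   Step 3b nucleus degeneration: demarcated -> superficial,
#           eroded -> squamous

#' Classifier thresholds
#'
#' The three quantitative thresholds that drive the flowchart. The defaults
#' are the published tutorial values: a parabasal cell has a maximum
#' diameter of 20 µm; cornification counts as "moderate to significant" from
#' two cornification lines upwards; a non-cornified cell whose nucleus area
#' is 79.5 µm² or larger is an intermediate cell. The 79.5 µm² default is
#' the 95th percentile of measured superficial-cell nucleus areas (see
#' [percentile_threshold()] for the calibration procedure).
#'
#' @param parabasal_max_diameter_um Maximum parabasal diameter in µm
#'   (default 20). Cells at exactly this diameter are still parabasal; only
#'   cells that exceed it proceed to the cornification step.
#' @param cornified_min_lines Minimum number of cornification lines for a
#'   "moderate to significant" grade (default 2, i.e. none-or-one line counts
#'   as "none or slight").
#' @param intermediate_min_nucleus_area_um2 Minimum nucleus area in µm² for
#'   an intermediate call (default 79.5).
#' @return An object of class `cyto_classifier_config`.
#' @examples
#' classifier_config()
#' classifier_config(intermediate_min_nucleus_area_um2 = 85)
#' @export
classifier_config <- function(parabasal_max_diameter_um = 20.0,
                              cornified_min_lines = 2L,
                              intermediate_min_nucleus_area_um2 = 79.5) {
  if (!is.numeric(parabasal_max_diameter_um) ||
      parabasal_max_diameter_um <= 0) {
    abort("`parabasal_max_diameter_um` must be strictly positive.",
          class = "cytovag_error_validation")
  }
  if (!is.numeric(cornified_min_lines) || cornified_min_lines < 1 ||
      cornified_min_lines != round(cornified_min_lines)) {
    abort("`cornified_min_lines` must be an integer >= 1.",
          class = "cytovag_error_validation")
  }
  if (!is.numeric(intermediate_min_nucleus_area_um2) ||
      intermediate_min_nucleus_area_um2 <= 0) {
    abort("`intermediate_min_nucleus_area_um2` must be strictly positive.",
          class = "cytovag_error_validation")
  }
  structure(
    list(parabasal_max_diameter_um = as.double(parabasal_max_diameter_um),
         cornified_min_lines = as.integer(cornified_min_lines),
         intermediate_min_nucleus_area_um2 =
           as.double(intermediate_min_nucleus_area_um2)),
    class = "cyto_classifier_config"
  )
}

#' @export
print.cyto_classifier_config <- function(x, ...) {
  cat("<cyto_classifier_config>\n")
  cat("  parabasal_max_diameter_um:        ", x$parabasal_max_diameter_um,
      "\n")
  cat("  cornified_min_lines:              ", x$cornified_min_lines, "\n")
  cat("  intermediate_min_nucleus_area_um2:",
      x$intermediate_min_nucleus_area_um2, "\n")
  invisible(x)
}

#' Read classifier thresholds from a YAML or JSON config file
#'
#' The file may contain any subset of the [classifier_config()] field names;
#' unspecified thresholds keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cyto_classifier_config`.
#' @export
read_classifier_config <- function(path) {
  vals <- read_config_file(path)
  allowed <- c("parabasal_max_diameter_um", "cornified_min_lines",
               "intermediate_min_nucleus_area_um2")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    abort(paste0("Unknown classifier config field(s): ",
                 paste(unknown, collapse = ", "), "."),
          class = "cytovag_error_validation")
  }
  do.call(classifier_config, vals)
}

#' Classify a single cell, with an audit trail
#'
#' Walks one cell through the flowchart and records every decision box
#' visited. For batch work use [classify_cells()], which takes a cell table
#' and vectorises the same logic.
#'
#' A cell at or below the parabasal diameter limit is parabasal regardless
#' of its other features; if such a cell nevertheless shows cornification
#' lines or an altered nucleus, a warning note is appended to the trace,
#' since validation measurements found no such cell among 200 small cells.
#' A large, non-cornified cell with no visible nucleus cannot be assessed at
#' the nuclear-area step and is routed to the nucleus-visibility step, where
#' it becomes squamous.
#'
#' @param diameter_um Cell diameter in µm (scalar).
#' @param cornification_lines Number of cornification lines (scalar integer).
#' @param nucleus_area_um2 Nucleus area in µm², or `NA` when absent.
#' @param nucleus_state `"absent"`, `"eroded"` or `"demarcated"`.
#' @param config A [classifier_config()].
#' @return A list with elements `class` (one of [CELL_CLASSES]) and `trace`,
#'   a tibble of `(step, outcome)` rows in flowchart order.
#' @examples
#' classify_cell(28, 1, 90, "demarcated")$class    # intermediate
#' classify_cell(45, 3, NA, "absent")$class        # squamous
#' @export
classify_cell <- function(diameter_um, cornification_lines,
                          nucleus_area_um2 = NA_real_,
                          nucleus_state = "demarcated",
                          config = classifier_config()) {
  cells <- cell_table(diameter_um = diameter_um,
                      cornification_lines = cornification_lines,
                      nucleus_area_um2 = nucleus_area_um2,
                      nucleus_state = nucleus_state)
  if (nrow(cells) != 1) {
    abort("`classify_cell()` takes a single cell; use `classify_cells()`.",
          class = "cytovag_error_validation")
  }
  res <- classify_cells(cells, config = config)
  list(class = res$class[[1]], trace = res$trace[[1]])
}

#' Classify every cell in a feature table
#'
#' Data-frame-first, vectorised flowchart traversal. The input is validated
#' against the cell-table schema; the result is the input with a `class`
#' column (factor over [CELL_CLASSES]) and a `trace` list-column of
#' per-cell decision traces appended, so calls compose with the pipe.
#'
#' @param cells A cell feature table (see [cell_table()]).
#' @param config A [classifier_config()].
#' @return The input tibble with `class` and `trace` columns added.
#' @examples
#' cell_table(diameter_um = c(15, 40), cornification_lines = c(0L, 2L),
#'            nucleus_area_um2 = c(55, 70),
#'            nucleus_state = c("demarcated", "demarcated")) |>
#'   classify_cells()
#' @export
classify_cells <- function(cells, config = classifier_config()) {
  cells <- validate_cell_table(cells)
  stopifnot(inherits(config, "cyto_classifier_config"))
  n <- nrow(cells)
  if (n == 0) {
    cells$class <- factor(character(), levels = CELL_CLASSES)
    cells$trace <- list()
    return(cells)
  }

  d <- cells$diameter_um
  lines <- cells$cornification_lines
  area <- cells$nucleus_area_um2
  state <- cells$nucleus_state

  small <- d <= config$parabasal_max_diameter_um
  cornified <- lines >= config$cornified_min_lines
  # Step 2a is only reachable for large, non-cornified cells with a visible
  # nucleus; an absent nucleus has no measurable area and falls to Step 3a.
  large_nucleated <- !small & !cornified & state != "absent"
  intermediate <- large_nucleated &
    area >= config$intermediate_min_nucleus_area_um2
  # everything else that is large reaches Step 3a
  at_3a <- !small & !intermediate
  squamous_3a <- at_3a & state == "absent"
  at_3b <- at_3a & state != "absent"
  superficial <- at_3b & state == "demarcated"
  squamous_3b <- at_3b & state == "eroded"

  cls <- character(n)
  cls[small] <- "parabasal"
  cls[intermediate] <- "intermediate"
  cls[superficial] <- "superficial"
  cls[squamous_3a | squamous_3b] <- "squamous"

  traces <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- list(c("step1", if (small[i]) {
      sprintf("diameter %.1f um <= %.1f um: parabasal", d[i],
              config$parabasal_max_diameter_um)
    } else {
      sprintf("diameter %.1f um exceeds %.1f um: continue", d[i],
              config$parabasal_max_diameter_um)
    }))
    if (small[i]) {
      if (lines[i] >= 1 || state[i] != "demarcated") {
        tr <- c(tr, list(c("step1", paste0(
          "warning: cell at or below the parabasal diameter limit shows ",
          "cornification or an altered nucleus"))))
      }
    } else {
      tr <- c(tr, list(c("step2", if (cornified[i]) {
        sprintf("%d cornification line(s): moderate to significant", lines[i])
      } else {
        sprintf("%d cornification line(s): none or slight", lines[i])
      })))
      if (!cornified[i]) {
        if (state[i] == "absent") {
          tr <- c(tr, list(c("step2a",
                             "no visible nucleus, area not assessable")))
        } else if (intermediate[i]) {
          tr <- c(tr, list(c("step2a", sprintf(
            "nucleus area %.1f um2 >= %.1f um2: intermediate", area[i],
            config$intermediate_min_nucleus_area_um2))))
        } else {
          tr <- c(tr, list(c("step2a", sprintf(
            "nucleus area %.1f um2 < %.1f um2: not intermediate", area[i],
            config$intermediate_min_nucleus_area_um2))))
        }
      }
      if (at_3a[i]) {
        tr <- c(tr, list(c("step3a", if (state[i] == "absent") {
          "no visible nucleus: squamous"
        } else {
          "nucleus visible: continue"
        })))
      }
      if (at_3b[i]) {
        tr <- c(tr, list(c("step3b", if (state[i] == "demarcated") {
          "nucleus definable and demarcated: superficial"
        } else {
          "nucleus eroded and only just visible: squamous"
        })))
      }
    }
    traces[[i]] <- tibble(step = map_chr(tr, 1), outcome = map_chr(tr, 2))
  }

  cells$class <- factor(cls, levels = CELL_CLASSES)
  cells$trace <- traces
  cells
}

#' Summarise a classified smear into a composition profile
#'
#' Aggregates a cell table into the per-class composition and the derived
#' fractions used by the cycle-staging rules. Cells are classified with
#' [classify_cells()] unless the table already carries a `class` column.
#'
#' The "pyknotic or absent" fraction proxies pyknosis by a nucleus area
#' below the intermediate threshold: a cell counts if its nucleus is eroded
#' or absent, or demarcated but with an area under
#' `intermediate_min_nucleus_area_um2`.
#'
#' @param cells A cell feature table.
#' @param config A [classifier_config()].
#' @param neutrophil_count Number of neutrophil granulocytes seen alongside
#'   the epithelial cells (default 0; the synthetic generator records this
#'   as an attribute which is picked up automatically).
#' @param neutrophil_presence_frac Minimum neutrophil-to-epithelial ratio for
#'   `neutrophils_present` (default 0.05).
#' @return An object of class `cyto_smear_profile`: a list with per-class
#'   `counts` and `proportions`, `n_cells`, `pyknotic_or_absent_fraction`,
#'   `anuclear_fraction`, `cornified_fraction`, `neutrophil_count` and
#'   `neutrophils_present`.
#' @export
smear_profile <- function(cells, config = classifier_config(),
                          neutrophil_count = NULL,
                          neutrophil_presence_frac = 0.05) {
  if (is.null(neutrophil_count)) {
    distract <- attr(cells, "distractors")
    neutrophil_count <- if (!is.null(distract)) {
      as.integer(distract[["neutrophils"]] %||% 0L)
    } else 0L
  }
  cells <- validate_cell_table(cells)
  if (nrow(cells) == 0) {
    abort("Cannot profile an empty smear: no cells supplied.",
          class = "cytovag_error_empty")
  }
  if (!"class" %in% names(cells)) {
    cells <- classify_cells(cells, config = config)
  }
  cls <- factor(as.character(cells$class), levels = CELL_CLASSES)
  counts <- table(cls)
  n <- nrow(cells)
  props <- as.numeric(counts) / n
  names(props) <- CELL_CLASSES

  absent <- cells$nucleus_state == "absent"
  eroded <- cells$nucleus_state == "eroded"
  small_nucleus <- !absent &
    cells$nucleus_area_um2 < config$intermediate_min_nucleus_area_um2
  pyk <- mean(absent | eroded | small_nucleus)
  cornified <- mean(cells$cornification_lines >= config$cornified_min_lines)

  structure(
    list(counts = setNames(as.integer(counts), CELL_CLASSES),
         proportions = props,
         n_cells = n,
         pyknotic_or_absent_fraction = pyk,
         anuclear_fraction = mean(absent),
         cornified_fraction = cornified,
         neutrophil_count = as.integer(neutrophil_count),
         neutrophils_present =
           neutrophil_count / n >= neutrophil_presence_frac),
    class = "cyto_smear_profile"
  )
}

#' @export
print.cyto_smear_profile <- function(x, ...) {
  cat("<cyto_smear_profile> of", x$n_cells, "cells\n")
  comp <- paste0(sprintf("%s %.1f%%", names(x$proportions),
                         100 * x$proportions), collapse = ", ")
  cat(" ", comp, "\n")
  cat(sprintf("  pyknotic/absent %.1f%%, anuclear %.1f%%, cornified %.1f%%\n",
              100 * x$pyknotic_or_absent_fraction,
              100 * x$anuclear_fraction, 100 * x$cornified_fraction))
  cat("  neutrophils:", x$neutrophil_count,
      if (x$neutrophils_present) "(present)" else "(not prominent)", "\n")
  invisible(x)
}

#' @rdname smear_profile
#' @param x A `cyto_smear_profile`.
#' @param ... Unused.
#' @method tidy cyto_smear_profile
#' @export
tidy.cyto_smear_profile <- function(x, ...) {
  tibble(class = CELL_CLASSES,
         count = as.integer(x$counts),
         proportion = as.numeric(x$proportions))
}

#' @rdname smear_profile
#' @method glance cyto_smear_profile
#' @export
glance.cyto_smear_profile <- function(x, ...) {
  tibble(n_cells = x$n_cells,
         pyknotic_or_absent_fraction = x$pyknotic_or_absent_fraction,
         anuclear_fraction = x$anuclear_fraction,
         cornified_fraction = x$cornified_fraction,
         neutrophil_count = x$neutrophil_count,
         neutrophils_present = x$neutrophils_present)
}
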