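# Seeded generator of labeled cell feature tables. Per-class feature priors
# follow the tutorial's measurements and the literature ranges; stage
# mixtures encode typical smear compositions across the estrous cycle. A
# margin buffer keeps draws away from the classifier's decision boundaries
# so that generated labels are recoverable by construction.

#' Synthetic smear generator configuration
#'
#' Per-class feature priors and per-stage composition for
#' [generate_cell_table()]. Defaults:
#'
#' * Diameters (µm, uniform): parabasal 10--20, intermediate 20--50,
#'   superficial 30--75, squamous 30--75, matching the literature ranges.
#' * Nucleus areas (µm², truncated normal): superficial mean 57.7, SD 13.8
#'   (the measured distribution on cornified cells), truncated at 0;
#'   intermediate mean 95 (the literature's ">90 µm²" nucleus), SD 15,
#'   truncated below at the 79.5 µm² intermediate threshold; parabasal mean
#'   60, SD 10; squamous eroded remnants mean 30, SD 8, truncated at 12.
#' * Cornification lines: parabasal always 0; intermediate 0 or 1
#'   (60/40); superficial and squamous uniform over 2--5.
#' * Nucleus state: parabasal, intermediate and superficial demarcated;
#'   squamous absent with probability 0.85, else an eroded remnant.
#' * Stage mixtures (parabasal/intermediate/superficial/squamous):
#'   anestrus 70/30/0/0; proestrus 20/40/35/5; estrus 0/0/30/70;
#'   early diestrus 20/40/30/10.
#' * Distractor rates (expected count per epithelial cell):
#'   erythrocytes peak in proestrus, neutrophils in early diestrus.
#'
#' The margin buffer is subtracted from class feature ranges at the decision
#' boundaries (the parabasal diameter limit and the intermediate nucleus-area
#' threshold) so that, with the default positive margin, every generated cell
#' is recovered exactly by [classify_cells()].
#'
#' @param diameter_ranges Named list of `c(min, max)` diameters in µm per
#'   class.
#' @param nucleus_area Named list of `list(mean, sd, lower, upper)` truncated
#'   normal parameters per class (µm²).
#' @param line_probs Named list of named probability vectors over line counts
#'   per class (names are the counts).
#' @param nucleus_state_probs Named list of named probability vectors over
#'   [NUCLEUS_STATES] per class.
#' @param stage_mixtures Named list (per stage in [CYCLE_STAGES]) of
#'   length-4 class-proportion vectors summing to 1, in [CELL_CLASSES] order.
#' @param distractor_rates Named list (per stage) of
#'   `c(erythrocytes = , neutrophils = )` expected counts per epithelial
#'   cell.
#' @param margin List with `diameter_um` and `nucleus_area_um2` boundary
#'   buffers (defaults 1 µm and 4 µm²); set both to 0 to sample right up to
#'   the decision boundaries.
#' @return An object of class `cyto_generator_config`.
#' @export
generator_config <- function(
    diameter_ranges = list(parabasal = c(10, 20),
                           intermediate = c(20, 50),
                           superficial = c(30, 75),
                           squamous = c(30, 75)),
    nucleus_area = list(
      parabasal = list(mean = 60, sd = 10, lower = 0, upper = Inf),
      intermediate = list(mean = 95, sd = 15, lower = 79.5, upper = Inf),
      superficial = list(mean = 57.7, sd = 13.8, lower = 0, upper = Inf),
      squamous = list(mean = 30, sd = 8, lower = 12, upper = Inf)),
    line_probs = list(parabasal = c("0" = 1),
                      intermediate = c("0" = 0.6, "1" = 0.4),
                      superficial = c("2" = 0.25, "3" = 0.25, "4" = 0.25,
                                      "5" = 0.25),
                      squamous = c("2" = 0.25, "3" = 0.25, "4" = 0.25,
                                   "5" = 0.25)),
    nucleus_state_probs = list(parabasal = c(demarcated = 1),
                               intermediate = c(demarcated = 1),
                               superficial = c(demarcated = 1),
                               squamous = c(absent = 0.85, eroded = 0.15)),
    stage_mixtures = list(anestrus = c(0.70, 0.30, 0, 0),
                          proestrus = c(0.20, 0.40, 0.35, 0.05),
                          estrus = c(0, 0, 0.30, 0.70),
                          early_diestrus = c(0.20, 0.40, 0.30, 0.10)),
    distractor_rates = list(
      anestrus = c(erythrocytes = 0.1, neutrophils = 0.2),
      proestrus = c(erythrocytes = 2.0, neutrophils = 0.02),
      estrus = c(erythrocytes = 0.5, neutrophils = 0.02),
      early_diestrus = c(erythrocytes = 0.3, neutrophils = 1.0)),
    margin = list(diameter_um = 1.0, nucleus_area_um2 = 4.0)) {
  for (cls in CELL_CLASSES) {
    rng <- diameter_ranges[[cls]]
    if (is.null(rng) || length(rng) != 2 || rng[1] >= rng[2] || rng[1] <= 0) {
      abort(paste0("`diameter_ranges$", cls,
                   "` must be a non-degenerate positive range."),
            class = "cytovag_error_validation")
    }
  }
  for (stage in names(stage_mixtures)) {
    mix <- stage_mixtures[[stage]]
    if (length(mix) != 4 || any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
      abort(paste0("`stage_mixtures$", stage,
                   "` must be 4 non-negative proportions summing to 1."),
            class = "cytovag_error_validation")
    }
  }
  if (margin$diameter_um < 0 || margin$nucleus_area_um2 < 0) {
    abort("`margin` buffers must be non-negative.",
          class = "cytovag_error_validation")
  }
  structure(
    list(diameter_ranges = diameter_ranges,
         nucleus_area = nucleus_area,
         line_probs = line_probs,
         nucleus_state_probs = nucleus_state_probs,
         stage_mixtures = stage_mixtures,
         distractor_rates = distractor_rates,
         margin = margin),
    class = "cyto_generator_config"
  )
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# class-specific diameter range with the margin buffer applied at the
# parabasal decision boundary
effective_diameter_range <- function(config, cls,
                                     boundary = classifier_config()) {
  rng <- config$diameter_ranges[[cls]]
  m <- config$margin$diameter_um
  lim <- boundary$parabasal_max_diameter_um
  if (abs(rng[2] - lim) < 1e-9) rng[2] <- rng[2] - m
  if (abs(rng[1] - lim) < 1e-9) rng[1] <- rng[1] + m
  if (rng[1] >= rng[2]) {
    abort("Margin buffer degenerates a diameter range; reduce `margin`.",
          class = "cytovag_error_validation")
  }
  rng
}

#' Draw nucleus areas from a class prior
#'
#' Samples nucleus areas (µm²) from the configured truncated-normal prior of
#' one cell class. For the intermediate class the margin buffer is added to
#' the lower truncation bound, as in [generate_cell_table()].
#'
#' @param class One of [CELL_CLASSES].
#' @param n Number of draws.
#' @param config A [generator_config()].
#' @param apply_margin Apply the boundary margin buffer (default `TRUE`).
#' @return Numeric vector of `n` areas.
#' @export
sample_nucleus_areas <- function(class, n, config = generator_config(),
                                 apply_margin = TRUE) {
  class <- match.arg(class, CELL_CLASSES)
  pr <- config$nucleus_area[[class]]
  lower <- pr$lower
  thr <- classifier_config()$intermediate_min_nucleus_area_um2
  if (apply_margin && abs(lower - thr) < 1e-9) {
    lower <- lower + config$margin$nucleus_area_um2
  }
  rtruncnorm(n, pr$mean, pr$sd, lower, pr$upper %||% Inf)
}

#' Generate a labeled synthetic cell table for one cycle stage
#'
#' Draws `n` cells whose class mixture follows the stage's configured
#' proportions and whose features follow the per-class priors, producing a
#' ground-truth `true_class` column alongside the standard cell-table
#' schema. With the default positive margin, [classify_cells()] recovers
#' `true_class` for every generated cell. Distractor (erythrocyte and
#' neutrophil) counts are drawn from Poisson rates per epithelial cell and
#' attached as the `distractors` attribute, which [smear_profile()] and
#' [render_smear()] pick up.
#'
#' @param stage One of [CYCLE_STAGES].
#' @param n Number of epithelial cells (`>= 0`).
#' @param config A [generator_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return A labeled cell table: the cell-table columns plus `true_class`,
#'   with attributes `stage` and `distractors`.
#' @examples
#' generate_cell_table("estrus", 5, seed = 1)
#' @export
generate_cell_table <- function(stage, n, config = generator_config(),
                                seed = NULL) {
  if (!is.character(stage) || length(stage) != 1 ||
      !stage %in% names(config$stage_mixtures)) {
    abort(paste0("Unknown stage ",
                 if (is.character(stage)) paste0('"', stage, '"') else "",
                 "; valid stages: ",
                 paste(names(config$stage_mixtures), collapse = ", "), "."),
          class = "cytovag_error_validation")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    abort("`n` must be a single non-negative integer.",
          class = "cytovag_error_validation")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)

  if (n == 0) {
    out <- cell_table(diameter_um = numeric(), cornification_lines = integer(),
                      nucleus_area_um2 = numeric(),
                      nucleus_state = character(), cell_id = character())
    out$true_class <- factor(character(), levels = CELL_CLASSES)
    attr(out, "stage") <- stage
    attr(out, "distractors") <- c(erythrocytes = 0L, neutrophils = 0L)
    return(out)
  }

  mix <- config$stage_mixtures[[stage]]
  cls <- sample(CELL_CLASSES, n, replace = TRUE, prob = mix)

  diameter <- numeric(n)
  lines <- integer(n)
  area <- rep(NA_real_, n)
  state <- character(n)
  for (cc in CELL_CLASSES) {
    idx <- which(cls == cc)
    if (length(idx) == 0) next
    rng <- effective_diameter_range(config, cc)
    diameter[idx] <- runif(length(idx), rng[1], rng[2])
    lp <- config$line_probs[[cc]]
    lines[idx] <- as.integer(sample(names(lp), length(idx), replace = TRUE,
                                    prob = lp))
    sp <- config$nucleus_state_probs[[cc]]
    state[idx] <- sample(names(sp), length(idx), replace = TRUE, prob = sp)
    nucleated <- idx[state[idx] != "absent"]
    if (length(nucleated) > 0) {
      area[nucleated] <- sample_nucleus_areas(cc, length(nucleated), config)
    }
  }

  out <- cell_table(diameter_um = diameter, cornification_lines = lines,
                    nucleus_area_um2 = area, nucleus_state = state)
  out$true_class <- factor(cls, levels = CELL_CLASSES)
  rates <- config$distractor_rates[[stage]] %||%
    c(erythrocytes = 0, neutrophils = 0)
  attr(out, "stage") <- stage
  attr(out, "distractors") <- c(
    erythrocytes = rpois(1, n * rates[["erythrocytes"]]),
    neutrophils = rpois(1, n * rates[["neutrophils"]]))
  out
}
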