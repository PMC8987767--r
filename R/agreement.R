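# Fleiss' kappa for a fixed number of raters assigning N subjects to k
# categories. Input is the N x k count matrix n_ij (raters who put subject i
# in category j); every row must sum to the common number of raters n.

#' Build a rating count matrix from a long ratings table
#'
#' Converts survey-style long data (one row per rater-by-subject decision)
#' into the N subjects x k categories count matrix that [fleiss_kappa()]
#' consumes. Every subject must be rated by the same number of distinct
#' raters, and no rater may rate the same subject twice.
#'
#' @param ratings A data frame with columns `subject_id`, `rater_id`,
#'   `category`.
#' @param categories Optional explicit category vector fixing column order
#'   (and admitting categories never used); defaults to first-appearance
#'   order.
#' @return An integer matrix with class `cyto_rating_matrix`, subjects as
#'   rownames, categories as colnames and the raters-per-subject count in
#'   attribute `n_raters`.
#' @examples
#' long <- tibble::tibble(
#'   subject_id = rep(c("s1", "s2"), each = 3),
#'   rater_id = rep(c("r1", "r2", "r3"), 2),
#'   category = c("A", "A", "B", "B", "B", "B"))
#' ratings_to_matrix(long)
#' @export
ratings_to_matrix <- function(ratings, categories = NULL) {
  required <- c("subject_id", "rater_id", "category")
  missing_cols <- setdiff(required, names(ratings))
  if (length(missing_cols) > 0) {
    abort(paste0("Ratings table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "cytovag_error_validation")
  }
  ratings <- as_tibble(ratings)
  dup <- duplicated(ratings[c("subject_id", "rater_id")])
  if (any(dup)) {
    offenders <- unique(ratings$subject_id[dup])
    abort(paste0("Duplicate (subject, rater) pair(s) for subject(s): ",
                 paste(offenders, collapse = ", "), "."),
          class = "cytovag_error_validation")
  }
  per_subject <- table(ratings$subject_id)
  if (length(unique(as.integer(per_subject))) != 1) {
    uneven <- names(per_subject)[per_subject != max(per_subject)]
    abort(paste0("Every subject must be rated by the same number of raters; ",
                 "offending subject(s): ",
                 paste(uneven, collapse = ", "), "."),
          class = "cytovag_error_validation")
  }
  cats <- categories %||% unique(as.character(ratings$category))
  unknown <- setdiff(unique(as.character(ratings$category)), cats)
  if (length(unknown) > 0) {
    abort(paste0("Categories not in the supplied category list: ",
                 paste(unknown, collapse = ", "), "."),
          class = "cytovag_error_validation")
  }
  subjects <- unique(as.character(ratings$subject_id))
  counts <- table(factor(ratings$subject_id, levels = subjects),
                  factor(ratings$category, levels = cats))
  m <- matrix(as.integer(counts), nrow = length(subjects),
              dimnames = list(subjects, cats))
  new_rating_matrix(m)
}

#' Construct a rating matrix from counts
#'
#' Validates an N x k matrix of rater counts (constant row sum, at least two
#' raters and two categories) and tags it for use with [fleiss_kappa()].
#'
#' @param counts A non-negative integer matrix, subjects in rows, categories
#'   in columns.
#' @return A `cyto_rating_matrix`.
#' @export
new_rating_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Rating counts must be non-negative integers.",
          class = "cytovag_error_validation")
  }
  if (ncol(counts) < 2) {
    abort("A rating matrix needs at least two categories.",
          class = "cytovag_error_validation")
  }
  row_sums <- rowSums(counts)
  if (length(unique(row_sums)) != 1) {
    abort("Every subject (row) must have the same total number of raters.",
          class = "cytovag_error_validation")
  }
  n <- unique(row_sums)
  if (n < 2) {
    abort("At least two raters per subject are required.",
          class = "cytovag_error_validation")
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("cyto_rating_matrix", "matrix", "array"),
            n_raters = as.integer(n))
}

#' Fleiss' kappa with all intermediate quantities
#'
#' Chance-corrected agreement for `n` raters assigning `N` subjects to `k`
#' categories. With `n_ij` the number of raters placing subject `i` in
#' category `j`:
#' per-subject agreement `P_i = sum_j n_ij (n_ij - 1) / (n (n - 1))`,
#' mean observed agreement `P_bar = mean(P_i)`, category prevalence
#' `p_j = sum_i n_ij / (N n)`, expected chance agreement
#' `P_e = sum_j p_j^2`, and `kappa = (P_bar - P_e) / (1 - P_e)`.
#'
#' When every rating falls in one single category `P_e = 1` and kappa is
#' undefined; a classed error (`cytovag_error_kappa_undefined`) is raised
#' whose message reports the observed agreement `P_bar`.
#'
#' @param counts A `cyto_rating_matrix` (see [new_rating_matrix()] /
#'   [ratings_to_matrix()]) or a plain count matrix with constant row sums.
#' @return An object of class `cyto_fleiss_kappa` holding `kappa`, `band`
#'   (see [interpret_kappa()]), `p_bar`, `p_e`, the per-subject agreement
#'   vector `p_i`, category proportions `p_j`, and the dimensions `n_subjects`,
#'   `n_raters`, `n_categories`. [tidy()] returns per-subject rows, [glance()]
#'   the one-row summary.
#' @examples
#' m <- rbind(c(9, 6, 1, 0, 0))  # 16 raters split over 5 categories
#' # per-subject agreement of that row:
#' fleiss_kappa(rbind(m, m))$p_i
#' @export
fleiss_kappa <- function(counts) {
  if (!inherits(counts, "cyto_rating_matrix")) {
    counts <- new_rating_matrix(counts)
  }
  n <- attr(counts, "n_raters")
  N <- nrow(counts)
  k <- ncol(counts)
  m <- unclass(counts)

  p_i <- rowSums(m * (m - 1)) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(m) / (N * n)
  p_e <- sum(p_j^2)

  if (p_e >= 1 - 1e-12) {
    abort(sprintf(paste0("Kappa is undefined: all ratings fall in a single ",
                         "category (expected agreement = 1). Observed mean ",
                         "agreement P_bar = %.6f."), p_bar),
          class = "cytovag_error_kappa_undefined",
          p_bar = p_bar)
  }
  kappa <- (p_bar - p_e) / (1 - p_e)

  structure(
    list(kappa = kappa,
         band = interpret_kappa(kappa),
         p_bar = p_bar,
         p_e = p_e,
         p_i = setNames(p_i, rownames(m)),
         p_j = setNames(p_j, colnames(m)),
         n_subjects = N, n_raters = n, n_categories = k),
    class = "cyto_fleiss_kappa"
  )
}

#' Interpretation band for a kappa value
#'
#' The conventional reading used alongside the statistic: 0 means agreement
#' no better than chance; values below 0.40 indicate poor agreement; values
#' above 0.75 good agreement; 1.0 perfect agreement. Values between 0.40 and
#' 0.75 (both boundaries included) are labelled moderate. Negative kappa
#' (worse than chance) is banded poor.
#'
#' @param kappa Numeric vector of kappa values, each `<= 1`.
#' @return Character vector over `"poor"`, `"moderate"`, `"good"`,
#'   `"perfect"`.
#' @examples
#' interpret_kappa(c(0.39, 0.533, 0.858, 1))
#' @export
interpret_kappa <- function(kappa) {
  if (!is.numeric(kappa) || any(is.na(kappa)) || any(kappa > 1 + 1e-12)) {
    abort("`kappa` must be numeric and cannot exceed 1.",
          class = "cytovag_error_domain")
  }
  dplyr::case_when(
    kappa >= 1 ~ "perfect",
    kappa > 0.75 ~ "good",
    kappa >= 0.40 ~ "moderate",
    .default = "poor"
  )
}

#' @export
print.cyto_fleiss_kappa <- function(x, ...) {
  cat("<cyto_fleiss_kappa>\n")
  cat(sprintf("  %d subjects, %d raters, %d categories\n",
              x$n_subjects, x$n_raters, x$n_categories))
  cat(sprintf("  kappa = %.4f (%s agreement)\n", x$kappa, x$band))
  cat(sprintf("  observed P_bar = %.4f, expected P_e = %.4f\n",
              x$p_bar, x$p_e))
  invisible(x)
}

#' @rdname fleiss_kappa
#' @param x A `cyto_fleiss_kappa` object.
#' @param ... Unused.
#' @method tidy cyto_fleiss_kappa
#' @export
tidy.cyto_fleiss_kappa <- function(x, ...) {
  tibble(subject = names(x$p_i) %||% as.character(seq_along(x$p_i)),
         agreement = as.numeric(x$p_i))
}

#' @rdname fleiss_kappa
#' @method glance cyto_fleiss_kappa
#' @export
glance.cyto_fleiss_kappa <- function(x, ...) {
  tibble(kappa = x$kappa, band = x$band, p_bar = x$p_bar, p_e = x$p_e,
         n_subjects = x$n_subjects, n_raters = x$n_raters,
         n_categories = x$n_categories)
}

#' Read a long-format ratings CSV
#'
#' Expects the columns `subject_id`, `rater_id`, `category`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_ratings <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  required <- c("subject_id", "rater_id", "category")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Ratings CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "cytovag_error_validation")
  }
  raw
}
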