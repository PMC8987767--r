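# Shared fixtures and independent oracles.

# the seven worked cells spanning every flowchart branch, with the class
# each should receive
worked_cells <- function() {
  cell_table(
    diameter_um = c(15, 20, 28, 28, 45, 45, 40),
    cornification_lines = c(0L, 0L, 1L, 1L, 3L, 3L, 2L),
    nucleus_area_um2 = c(50, 55, 90, 60, NA, 30, 70),
    nucleus_state = c("demarcated", "demarcated", "demarcated",
                      "demarcated", "absent", "eroded", "demarcated"))
}

worked_classes <- function() {
  c("parabasal", "parabasal", "intermediate", "superficial",
    "squamous", "squamous", "superficial")
}

# brute-force per-subject agreement: expand each row into individual rater
# assignments and count agreeing ordered rater pairs
oracle_p_i <- function(counts) {
  n <- sum(counts[1, ])
  apply(counts, 1, function(row) {
    assignments <- rep(seq_along(row), times = row)
    agree <- 0L
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a != b && assignments[a] == assignments[b]) agree <- agree + 1L
      }
    }
    agree / (n * (n - 1))
  })
}

# random valid rating matrix for property tests
random_rating_matrix <- function(N, n, k) {
  m <- matrix(0L, N, k)
  for (i in seq_len(N)) {
    picks <- sample.int(k, n, replace = TRUE)
    m[i, ] <- tabulate(picks, nbins = k)
  }
  m
}

# single-class generator config without distractors, for targeted renders
single_class_config <- function(class, ...) {
  mix <- setNames(rep(0, 4), CELL_CLASSES)
  mix[class] <- 1
  generator_config(
    stage_mixtures = list(only = unname(mix)),
    distractor_rates = list(only = c(erythrocytes = 0, neutrophils = 0)),
    ...)
}
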