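test_that("long ratings tables convert to count matrices", {
  long <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 3),
    rater_id = rep(c("r1", "r2", "r3"), 2),
    category = rep("A", 6))
  m <- ratings_to_matrix(long, categories = c("A", "B"))
  expect_equal(unclass(m)[, ], matrix(c(3L, 3L, 0L, 0L), 2,
                                      dimnames = list(c("s1", "s2"),
                                                      c("A", "B"))))
  expect_equal(attr(m, "n_raters"), 3L)

  # survey-sized fixture: 8 subjects x 16 raters
  set.seed(42)
  survey <- tidyr::expand_grid(subject_id = paste0("cell_", 1:8),
                               rater_id = paste0("vet_", 1:16))
  survey$category <- sample(c("parabasal", "intermediate", "superficial",
                              "squamous"), nrow(survey), replace = TRUE)
  ms <- ratings_to_matrix(survey)
  expect_equal(unname(rowSums(ms)), rep(16, 8))
  expect_equal(dim(ms), c(8L, 4L))
})

test_that("structural problems in ratings tables are rejected", {
  uneven <- tibble::tibble(
    subject_id = c("s1", "s1", "s2", "s2", "s2"),
    rater_id = c("r1", "r2", "r1", "r2", "r3"),
    category = "A")
  expect_error(ratings_to_matrix(uneven), "s1",
               class = "cytovag_error_validation")
  dup <- tibble::tibble(subject_id = c("s1", "s1"),
                        rater_id = c("r1", "r1"),
                        category = c("A", "B"))
  expect_error(ratings_to_matrix(dup), "Duplicate",
               class = "cytovag_error_validation")
})

test_that("unanimous ratings give kappa exactly 1", {
  m <- matrix(0L, 10, 2)
  m[1:6, 1] <- 5L
  m[7:10, 2] <- 5L
  fk <- fleiss_kappa(m)
  expect_identical(fk$kappa, 1)
  expect_equal(fk$band, "perfect")
  expect_equal(unname(fk$p_i), rep(1, 10))
})

test_that("all ratings in one category raise the undefined-kappa error", {
  m <- matrix(c(4L, 0L, 4L, 0L), 2, byrow = TRUE)
  err <- expect_error(fleiss_kappa(m),
                      class = "cytovag_error_kappa_undefined")
  expect_equal(err$p_bar, 1)
  expect_match(conditionMessage(err), "P_bar")
})

test_that("the survey's split row reproduces its per-subject agreement", {
  # one cell judged intermediate by 9, parabasal by 6, basal by 1 of 16
  row <- c(9L, 6L, 1L, 0L, 0L)
  m <- rbind(row, row)
  fk <- fleiss_kappa(m)
  expect_equal(unname(fk$p_i[1]), 102 / 240, tolerance = 1e-12)
  expect_equal(unname(fk$p_i[1]), 0.425, tolerance = 1e-12)
  expect_equal(unname(fk$p_i[1]), mean(oracle_p_i(m)), tolerance = 1e-12)
})

test_that("formula agreement matches brute-force pair counting", {
  set.seed(7)
  for (case in 1:60) {
    N <- sample(1:6, 1)
    n <- sample(2:5, 1)
    k <- sample(2:4, 1)
    m <- random_rating_matrix(N, n, k)
    fk <- tryCatch(fleiss_kappa(m),
                   cytovag_error_kappa_undefined = function(e) NULL)
    if (is.null(fk)) next
    expect_equal(unname(fk$p_i), unname(oracle_p_i(m)), tolerance = 1e-12)
  }
})

test_that("kappa is invariant to subject and category permutations", {
  set.seed(11)
  m <- random_rating_matrix(8, 4, 3)
  fk <- fleiss_kappa(m)
  expect_equal(fleiss_kappa(m[sample(8), ])$kappa, fk$kappa)
  expect_equal(fleiss_kappa(m[, sample(3)])$kappa, fk$kappa)
  # an unused category changes nothing
  expect_equal(fleiss_kappa(cbind(m, 0L))$kappa, fk$kappa)
})

test_that("uniform random ratings give kappa near zero", {
  set.seed(3)
  m <- random_rating_matrix(500, 5, 4)
  expect_equal(fleiss_kappa(m)$kappa, 0, tolerance = 0.03)
})

test_that("interpretation bands follow the stated rule", {
  expect_equal(interpret_kappa(c(-0.2, 0, 0.39)), rep("poor", 3))
  expect_equal(interpret_kappa(c(0.40, 0.412, 0.533, 0.75)),
               rep("moderate", 4))
  expect_equal(interpret_kappa(c(0.751, 0.858, 0.999)), rep("good", 3))
  expect_equal(interpret_kappa(1), "perfect")
  expect_error(interpret_kappa(1.2), class = "cytovag_error_domain")
})

test_that("tidy and glance expose the agreement quantities", {
  m <- rbind(c(3L, 2L), c(5L, 0L), c(1L, 4L))
  fk <- fleiss_kappa(m)
  td <- tidy(fk)
  expect_equal(nrow(td), 3)
  expect_true(all(td$agreement >= 0 & td$agreement <= 1))
  gl <- glance(fk)
  expect_equal(gl$kappa, fk$kappa)
  expect_equal(sum(fk$p_j), 1)
})
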