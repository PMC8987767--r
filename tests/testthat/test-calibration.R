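test_that("percentile threshold handles canonical samples", {
  expect_equal(percentile_threshold(rep(50, 4))$threshold, 50)
  expect_equal(percentile_threshold(1:100)$threshold, 95.05)
  r <- percentile_threshold(1:100)
  expect_equal(r$sample_size, 100L)
  expect_equal(r$mean_area, 50.5)
  expect_equal(r$sd_area, sd(1:100))
})

test_that("percentile threshold recovers the analytic normal quantile", {
  set.seed(1)
  areas <- rnorm(1e5, 57.7, 13.8)
  areas <- areas[areas > 0]
  thr <- percentile_threshold(areas)$threshold
  expect_equal(thr, 57.7 + qnorm(0.95) * 13.8, tolerance = 0.3 / 80)
})

test_that("percentile threshold is monotone in q and order-invariant", {
  set.seed(2)
  x <- runif(500, 20, 120)
  qs <- c(10, 25, 50, 75, 90, 99)
  thrs <- vapply(qs, function(q) percentile_threshold(x, q)$threshold,
                 numeric(1))
  expect_true(all(diff(thrs) >= 0))
  expect_equal(percentile_threshold(sample(x), 95)$threshold,
               percentile_threshold(x, 95)$threshold)
  expect_true(thrs[1] >= min(x) && thrs[length(qs)] <= max(x))
  expect_equal(percentile_threshold(x, 99.999)$threshold, max(x),
               tolerance = 1e-2)
})

test_that("degenerate calibration inputs raise validation errors", {
  expect_error(percentile_threshold(42), class = "cytovag_error_validation")
  expect_error(percentile_threshold(c(1, NA, 3)),
               class = "cytovag_error_validation")
  expect_error(percentile_threshold(c(1, Inf)),
               class = "cytovag_error_validation")
  expect_error(percentile_threshold(1:10, q = 0),
               class = "cytovag_error_validation")
  expect_error(percentile_threshold(1:10, q = 100),
               class = "cytovag_error_validation")
})

test_that("calibration can select measurable cells from a feature table", {
  cells <- cell_table(
    diameter_um = c(40, 45, 50, 30),
    cornification_lines = c(2L, 3L, 1L, 2L),
    nucleus_area_um2 = c(50, 60, 70, NA),
    nucleus_state = c("demarcated", "demarcated", "demarcated", "absent"))
  # only the two cornified cells with demarcated nuclei qualify
  r <- percentile_threshold(cells, q = 50)
  expect_equal(r$sample_size, 2L)
  expect_equal(r$threshold, 55)
})

test_that("generator superficial nuclei calibrate near the tutorial cut", {
  set.seed(9)
  areas <- sample_nucleus_areas("superficial", 10000)
  thr <- percentile_threshold(areas)$threshold
  expect_gt(thr, 75)
  expect_lt(thr, 85)
})

test_that("the small-cell rule validates cleanly on generated parabasals", {
  tb <- generate_cell_table("only", 200, single_class_config("parabasal"),
                            seed = 4)
  rep <- validate_parabasal_rule(tb)
  expect_true(rep$rule_holds)
  expect_equal(rep$violation_fraction, 0)
  expect_equal(rep$n_evaluable, 200L)
})

test_that("the small-cell rule reports violations and empty samples", {
  bad <- cell_table(diameter_um = 15, cornification_lines = 2L,
                    nucleus_area_um2 = 50, nucleus_state = "demarcated")
  rep <- validate_parabasal_rule(bad)
  expect_false(rep$rule_holds)
  expect_equal(rep$violation_fraction, 1)

  big <- cell_table(diameter_um = c(25, 30), cornification_lines = c(0L, 0L),
                    nucleus_area_um2 = c(90, 95),
                    nucleus_state = c("demarcated", "demarcated"))
  rep2 <- validate_parabasal_rule(big)
  expect_false(rep2$evaluable)
  expect_equal(rep2$n_evaluable, 0L)
  expect_true(is.na(rep2$rule_holds))
})
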