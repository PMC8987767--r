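test_that("diameter/area conversion matches the circular-nucleus values", {
  expect_equal(round(diameter_to_area(7), 1), 38.5)
  expect_equal(round(diameter_to_area(11), 1), 95.0)
  expect_equal(diameter_to_area(0), 0)
  expect_equal(area_to_diameter(0), 0)
  expect_equal(area_to_diameter(38.48), 7.0, tolerance = 1e-3)
  expect_equal(area_to_diameter(95.03), 11.0, tolerance = 1e-3)
})

test_that("conversion round-trips across the working range", {
  d <- seq(0, 1e4, length.out = 401)
  expect_equal(area_to_diameter(diameter_to_area(d)), d,
               tolerance = 1e-9)
  a <- seq(0, 1e4, length.out = 401)
  expect_equal(diameter_to_area(area_to_diameter(a)), a,
               tolerance = 1e-9)
  expect_error(diameter_to_area(-1), class = "cytovag_error_domain")
  expect_error(area_to_diameter(-0.1), class = "cytovag_error_domain")
})

test_that("the flowchart assigns the expected class on every branch", {
  cells <- worked_cells()
  res <- classify_cells(cells)
  expect_equal(as.character(res$class), worked_classes())
  # single-cell interface agrees
  for (i in seq_len(nrow(cells))) {
    one <- classify_cell(cells$diameter_um[i], cells$cornification_lines[i],
                         cells$nucleus_area_um2[i], cells$nucleus_state[i])
    expect_identical(as.character(one$class), worked_classes()[i])
  }
})

test_that("decision boundaries behave as printed", {
  # cells must exceed 20 um to leave the parabasal box
  expect_equal(as.character(classify_cell(20, 3, 30, "eroded")$class),
               "parabasal")
  expect_equal(as.character(classify_cell(20.01, 3, 30, "eroded")$class),
               "squamous")
  # nucleus area >= 79.5 um2 is intermediate, anything below falls through
  expect_equal(as.character(classify_cell(30, 0, 79.5, "demarcated")$class),
               "intermediate")
  expect_equal(as.character(classify_cell(30, 0, 79.49, "demarcated")$class),
               "superficial")
  # large non-cornified cell with no visible nucleus skips the area box
  expect_equal(as.character(classify_cell(30, 0, NA, "absent")$class),
               "squamous")
})

test_that("monotonicity holds at both thresholds", {
  # shrinking the diameter across 20 um can only change the class to
  # parabasal
  for (lines in c(0L, 3L)) {
    for (state in c("demarcated", "eroded")) {
      above <- classify_cell(20.5, lines, 60, state)$class
      below <- classify_cell(19.5, lines, 60, state)$class
      expect_equal(as.character(below), "parabasal")
      expect_true(as.character(above) != "parabasal")
    }
  }
  # growing the nucleus across 79.5 um2 flips superficial -> intermediate
  # for non-cornified demarcated cells, and nothing else
  lo <- classify_cell(35, 1, 70, "demarcated")$class
  hi <- classify_cell(35, 1, 85, "demarcated")$class
  expect_equal(as.character(c(lo, hi)), c("superficial", "intermediate"))
})

test_that("traces follow flowchart order and flag anomalous small cells", {
  tr <- classify_cell(40, 2, 70, "demarcated")$trace
  expect_equal(tr$step, c("step1", "step2", "step3a", "step3b"))
  tr2 <- classify_cell(28, 0, 60, "demarcated")$trace
  expect_equal(tr2$step, c("step1", "step2", "step2a", "step3a", "step3b"))
  # a small cell showing cornification is parabasal but carries a warning
  res <- classify_cell(15, 2, 50, "demarcated")
  expect_equal(as.character(res$class), "parabasal")
  expect_true(any(grepl("warning", res$trace$outcome)))
  # an unremarkable small cell does not
  res2 <- classify_cell(15, 0, 50, "demarcated")
  expect_false(any(grepl("warning", res2$trace$outcome)))
})

test_that("invalid records are rejected with field-naming errors", {
  expect_error(
    cell_table(diameter_um = 30, cornification_lines = 0L,
               nucleus_area_um2 = 50, nucleus_state = "absent"),
    "nucleus_area_um2", class = "cytovag_error_validation")
  expect_error(
    cell_table(diameter_um = 30, cornification_lines = 0L,
               nucleus_area_um2 = NA, nucleus_state = "demarcated"),
    "nucleus_area_um2", class = "cytovag_error_validation")
  expect_error(
    cell_table(diameter_um = -2, cornification_lines = 0L,
               nucleus_area_um2 = 50, nucleus_state = "demarcated"),
    "diameter_um", class = "cytovag_error_validation")
  expect_error(
    cell_table(diameter_um = 30, cornification_lines = -1L,
               nucleus_area_um2 = 50, nucleus_state = "demarcated"),
    "cornification_lines", class = "cytovag_error_validation")
  expect_error(
    cell_table(diameter_um = 30, cornification_lines = 0L,
               nucleus_area_um2 = 50, nucleus_state = "pyknotic"),
    "nucleus_state", class = "cytovag_error_validation")
})

test_that("classification ignores cell ids and input order", {
  cells <- worked_cells()
  shuffled <- cells[c(4, 1, 7, 3, 6, 2, 5), ]
  shuffled$cell_id <- paste0("renamed_", seq_len(7))
  res <- classify_cells(shuffled)
  expect_equal(as.character(res$class), worked_classes()[c(4, 1, 7, 3, 6,
                                                           2, 5)])
})

test_that("smear profiles aggregate classified cells correctly", {
  # degenerate composition
  sq <- cell_table(diameter_um = rep(45, 10),
                   cornification_lines = rep(3L, 10),
                   nucleus_area_um2 = rep(NA_real_, 10),
                   nucleus_state = rep("absent", 10))
  p <- smear_profile(sq)
  expect_equal(unname(p$proportions["squamous"]), 1)
  expect_equal(sum(p$proportions), 1)
  expect_equal(p$anuclear_fraction, 1)

  # the worked examples
  p7 <- smear_profile(worked_cells())
  expect_equal(unname(p7$counts),
               c(2L, 1L, 2L, 2L))

  # single record
  one <- smear_profile(worked_cells()[3, ])
  expect_equal(unname(one$proportions["intermediate"]), 1)

  expect_error(smear_profile(worked_cells()[0, ]),
               class = "cytovag_error_empty")
})
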