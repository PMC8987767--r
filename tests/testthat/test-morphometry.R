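test_that("blank and degenerate images segment to nothing", {
  blank <- matrix(0.95, 100, 100)
  segs <- segment_cells(blank, microns_per_pixel = 0.5)
  expect_equal(nrow(segs), 0)
  m <- measure_smear(blank, microns_per_pixel = 0.5)
  expect_equal(nrow(m), 0)
  expect_equal(nrow(attr(m, "exclusions")), 0)
  expect_error(segment_cells(blank), class = "cytovag_error_validation")
})

test_that("well-separated cells are segmented without flags", {
  tb <- generate_cell_table("proestrus", 5, seed = 1)
  smear <- render_smear(tb, render_config(canvas_px = 600), seed = 2,
                        distractors = c(erythrocytes = 0, neutrophils = 0))
  segs <- segment_cells(smear)
  expect_equal(nrow(segs), 5)
  expect_true(all(!segs$excluded))
  expect_true(all(!segs$touches_border))
  expect_true(all(segs$solidity > 0.8, na.rm = TRUE))
})

test_that("border-touching regions are flagged and excluded", {
  img <- matrix(0.95, 120, 120)
  # a 30-px-radius cell hanging off the left edge
  for (r in 1:120) {
    for (c in 1:40) {
      if ((r - 60)^2 + (c - 0)^2 <= 30^2) img[r, c] <- 0.7
    }
  }
  segs <- segment_cells(img, microns_per_pixel = 0.5)
  expect_equal(nrow(segs), 1)
  expect_true(segs$touches_border[1])
  expect_true(segs$excluded[1])
  expect_equal(segs$exclusion_reason[1], "border")
})

test_that("distractors fall below the minimum-size filter", {
  tb <- generate_cell_table("proestrus", 3, seed = 3)
  smear <- render_smear(tb, render_config(canvas_px = 800), seed = 4,
                        distractors = c(erythrocytes = 50, neutrophils = 5))
  meas <- measure_smear(smear)
  expect_equal(nrow(meas), 3)
  excl <- attr(meas, "exclusions")
  expect_true(all(excl$exclusion_reason == "debris"))
  expect_gte(nrow(excl), 50)
})

test_that("a rendered cell measures back to its recorded features", {
  tb <- cell_table(diameter_um = 40, cornification_lines = 0L,
                   nucleus_area_um2 = 55, nucleus_state = "demarcated")
  smear <- render_smear(tb, render_config(canvas_px = 160), seed = 5)
  meas <- measure_smear(smear)
  expect_equal(nrow(meas), 1)
  expect_equal(meas$diameter_um, 40, tolerance = 2 / 40)
  expect_equal(meas$nucleus_area_um2, 55, tolerance = 5 / 55)
  expect_equal(meas$nucleus_state, "demarcated")
  expect_equal(meas$cornification_lines, 0L)
})

test_that("anuclear and eroded cells measure to the right nucleus state", {
  sq <- cell_table(diameter_um = 45, cornification_lines = 3L,
                   nucleus_area_um2 = NA, nucleus_state = "absent")
  smear <- render_smear(sq, render_config(canvas_px = 180), seed = 6)
  meas <- measure_smear(smear)
  expect_equal(meas$nucleus_state, "absent")
  expect_true(is.na(meas$nucleus_area_um2))

  er <- cell_table(diameter_um = 45, cornification_lines = 2L,
                   nucleus_area_um2 = 30, nucleus_state = "eroded")
  smear2 <- render_smear(er, render_config(canvas_px = 180), seed = 7)
  meas2 <- measure_smear(smear2)
  expect_equal(meas2$nucleus_state, "eroded")
})

test_that("nucleus-area estimation is unbiased over many cells", {
  cfg <- single_class_config("superficial")
  tb <- generate_cell_table("only", 100, cfg, seed = 8)
  smear <- render_smear(tb, seed = 9)
  meas <- measure_smear(smear)
  m <- match_to_ground_truth(meas, smear)
  truth <- tb$nucleus_area_um2[match(m$true_cell_id, tb$cell_id)]
  rel_err <- (mean(m$nucleus_area_um2, na.rm = TRUE) - mean(truth)) /
    mean(truth)
  expect_lt(abs(rel_err), 0.02)
})

test_that("measurements are scale-equivariant", {
  tb <- cell_table(diameter_um = c(40, 36), cornification_lines = c(0L, 0L),
                   nucleus_area_um2 = c(60, 85),
                   nucleus_state = c("demarcated", "demarcated"))
  fine <- measure_smear(render_smear(
    tb, render_config(canvas_px = 260, microns_per_pixel = 0.5), seed = 10))
  coarse <- measure_smear(render_smear(
    tb, render_config(canvas_px = 130, microns_per_pixel = 1.0), seed = 10))
  fine <- fine[order(fine$diameter_um), ]
  coarse <- coarse[order(coarse$diameter_um), ]
  expect_equal(coarse$diameter_um, fine$diameter_um, tolerance = 0.05)
  expect_equal(coarse$nucleus_area_um2, fine$nucleus_area_um2,
               tolerance = 0.05)
})

test_that("the full render-measure-classify loop recovers most labels", {
  tb <- generate_cell_table("proestrus", 100, seed = 11)
  smear <- render_smear(tb, seed = 12)
  meas <- measure_smear(smear)
  m <- match_to_ground_truth(meas, smear)
  cls <- classify_cells(m)
  acc <- mean(as.character(cls$class) == m$true_class)
  expect_gte(acc, 0.90)
  expect_equal(nrow(m), 100)
})
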