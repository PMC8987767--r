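estrus_profile <- function(...) {
  as_smear_profile(...)
}

test_that("the antonov rule needs full cornified composition and pyknosis", {
  pos <- as_smear_profile(c(superficial = 0.4, squamous = 0.6),
                          pyknotic_or_absent_fraction = 0.85)
  expect_equal(call_estrus(pos, "antonov")$stage, "estrus_positive")

  # 80% pyknotic exactly fails the strict inequality
  borderline <- as_smear_profile(c(superficial = 0.4, squamous = 0.6),
                                 pyknotic_or_absent_fraction = 0.80)
  expect_equal(call_estrus(borderline, "antonov")$stage, "estrus_negative")

  incomplete <- as_smear_profile(c(superficial = 0.9, intermediate = 0.1),
                                 pyknotic_or_absent_fraction = 0.9)
  expect_equal(call_estrus(incomplete, "antonov")$stage, "estrus_negative")
})

test_that("the feldman rule is strict at 90%", {
  at90 <- as_smear_profile(c(superficial = 0.90, intermediate = 0.10))
  expect_equal(call_estrus(at90, "feldman90")$stage, "estrus_negative")
  above <- as_smear_profile(c(superficial = 0.905, intermediate = 0.095))
  expect_equal(call_estrus(above, "feldman90")$stage, "estrus_positive")
})

test_that("the kustritz rule needs total cornification and >50% squames", {
  pos <- as_smear_profile(c(superficial = 0.45, squamous = 0.55),
                          cornified_fraction = 1, anuclear_fraction = 0.51)
  expect_equal(call_estrus(pos, "kustritz")$stage, "estrus_positive")
  half <- as_smear_profile(c(superficial = 0.5, squamous = 0.5),
                           cornified_fraction = 1, anuclear_fraction = 0.50)
  expect_equal(call_estrus(half, "kustritz")$stage, "estrus_negative")
  uncornified <- as_smear_profile(c(superficial = 0.4, squamous = 0.6),
                                  cornified_fraction = 0.99,
                                  anuclear_fraction = 0.6)
  expect_equal(call_estrus(uncornified, "kustritz")$stage, "estrus_negative")
})

test_that("an all-parabasal smear is never estrus", {
  p <- as_smear_profile(c(parabasal = 1))
  for (rs in c("antonov", "feldman90", "kustritz")) {
    expect_equal(call_estrus(p, rs)$stage, "estrus_negative")
  }
  expect_error(call_estrus(p, "schutte"), "valid",
               class = "cytovag_error_validation")
})

test_that("every stage call reports its criteria evaluations", {
  p <- as_smear_profile(c(superficial = 0.4, squamous = 0.6),
                        pyknotic_or_absent_fraction = 0.85)
  call <- call_estrus(p, "antonov")
  expect_gte(nrow(tidy(call)), 1)
  expect_true(all(c("criterion", "observed", "threshold", "pass") %in%
                  names(tidy(call))))
  expect_equal(glance(call)$stage, "estrus_positive")
})

test_that("diestrus onset needs both the drop and the neutrophils", {
  prev <- as_smear_profile(c(superficial = 0.55, squamous = 0.40,
                             intermediate = 0.05))
  cur_drop <- as_smear_profile(c(superficial = 0.40, squamous = 0.30,
                                 intermediate = 0.30),
                               neutrophils_present = TRUE)
  expect_equal(call_diestrus_onset(cur_drop, prev)$stage, "diestrus_onset")

  cur_small <- as_smear_profile(c(superficial = 0.50, squamous = 0.30,
                                  intermediate = 0.20),
                                neutrophils_present = TRUE)
  expect_equal(call_diestrus_onset(cur_small, prev)$stage, "indeterminate")

  cur_no_neu <- as_smear_profile(c(superficial = 0.30, squamous = 0.30,
                                   intermediate = 0.40),
                                 neutrophils_present = FALSE)
  expect_equal(call_diestrus_onset(cur_no_neu, prev)$stage, "indeterminate")
})

test_that("relative-drop mode measures the decline proportionally", {
  prev <- as_smear_profile(c(superficial = 0.50, intermediate = 0.50))
  cur <- as_smear_profile(c(superficial = 0.38, intermediate = 0.62),
                          neutrophils_present = TRUE)
  # absolute drop 12 points fails, relative drop 24% passes
  expect_equal(call_diestrus_onset(cur, prev)$stage, "indeterminate")
  expect_equal(call_diestrus_onset(cur, prev, relative = TRUE)$stage,
               "diestrus_onset")
})

test_that("estrus calls are monotone in the cornification fractions", {
  set.seed(21)
  for (i in 1:40) {
    sup <- runif(1)
    sq <- runif(1, 0, 1 - sup)
    base <- as_smear_profile(
      c(superficial = sup, squamous = sq,
        intermediate = 1 - sup - sq),
      pyknotic_or_absent_fraction = runif(1),
      anuclear_fraction = runif(1),
      cornified_fraction = runif(1))
    for (rs in c("antonov", "feldman90", "kustritz")) {
      if (call_estrus(base, rs)$stage == "estrus_positive") {
        # push every relevant fraction up; the call must stay positive
        better <- as_smear_profile(
          c(superficial = sup + (1 - sup - sq) / 2,
            squamous = sq + (1 - sup - sq) / 2),
          pyknotic_or_absent_fraction =
            min(1, base$pyknotic_or_absent_fraction + 0.1),
          anuclear_fraction = min(1, base$anuclear_fraction + 0.1),
          cornified_fraction = min(1, base$cornified_fraction + 0.1))
        expect_equal(call_estrus(better, rs)$stage, "estrus_positive")
      }
    }
  }
})

test_that("generated smears stage as expected", {
  hits <- 0
  for (s in 1:5) {
    tb <- generate_cell_table("estrus", 200, seed = s)
    call <- call_estrus(smear_profile(tb), "kustritz")
    hits <- hits + (call$stage == "estrus_positive")
  }
  expect_gte(hits, 5 * 0.95 - 1)

  for (s in 1:3) {
    an <- smear_profile(generate_cell_table("anestrus", 200, seed = s))
    for (rs in c("antonov", "feldman90", "kustritz")) {
      expect_equal(call_estrus(an, rs)$stage, "estrus_negative")
    }
  }
})
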