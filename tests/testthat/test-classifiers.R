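test_that("block summaries average and maximize over the anatomical blocks", {
  bs <- block_summary(profile(4, 4, 4, 4, 4, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(bs$caudal_mean, 4)
  expect_equal(bs$limbic_mean, 0)
  expect_equal(bs$neocortical_mean, 0)

  bs <- block_summary(profile(0, 0, 1, 0, 1, 4, 2, 3, 2, 1, 1, 0))
  expect_equal(bs$caudal_mean, 0.4)
  expect_equal(bs$limbic_mean, 2.75)
  expect_equal(bs$neocortical_mean, 2 / 3)
  expect_equal(bs$limbic_max, 4)

  bs <- block_summary(profile(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_true(all(c(bs$caudal_mean, bs$limbic_mean, bs$neocortical_mean) == 0))

  # missing block: zero stats plus the missing flag; means skip NA regions
  p <- profile(1, NA, 2, NA, 1, NA, NA, NA, NA, 0, 0, 1)
  bs <- block_summary(p)
  expect_equal(bs$caudal_mean, 4 / 3)
  expect_true(bs$limbic_missing)
  expect_equal(bs$limbic_mean, 0)

  expect_error(block_summary(rep(NA_real_, 12)), "missing")
})

test_that("progression classification follows the block-dominance rules", {
  expect_equal(as.character(classify_progression(rep(0, 12))), "none")
  expect_equal(as.character(classify_progression(rep(4, 12))), "undetermined")
  expect_equal(as.character(classify_progression(
    profile(4, 3, 4, 3, 3, 2, 1, 2, 1, 1, 0, 0))), "caudo_rostral")
  expect_equal(as.character(classify_progression(
    profile(0, 0, 1, 0, 1, 4, 2, 3, 2, 1, 1, 0))), "amygdala_based")

  # exact block-mean tie: amygdala > medulla decides, else caudo-rostral
  tie_amy <- profile(0, 0, 1, 0, 4, 2, 1, 1, 0, 0, 0, 0)  # both means 1
  expect_equal(as.character(classify_progression(tie_amy)), "amygdala_based")
  tie_med <- profile(0, 0, 4, 0, 1, 1, 1, 1, 1, 0, 0, 0)
  expect_equal(as.character(classify_progression(tie_med)), "caudo_rostral")

  # missing comparator block falls back to medulla-vs-amygdala
  fallback <- profile(NA, NA, NA, NA, NA, 3, 1, 0, 0, 1, 0, 0)
  expect_equal(as.character(classify_progression(fallback)), "amygdala_based")

  expect_error(classify_progression(rep(NA_real_, 12)), "missing")
  expect_error(classify_progression(c(1, 2, 3)), "12 scores")
  expect_error(classify_progression(profile(7, rep(0, 11))), "0-4")
})

test_that("DLB Consortium typing applies its precedence rules", {
  cases <- list(
    list(profile(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0), "none"),
    list(profile(1, 0, 2, 1, 0, 0, 0, 0, 0, 0, 0, 0), "non_classifiable"),
    list(profile(0, 0, 0, 0, 0, 3, 0, 0, 0, 0, 0, 0), "amygdala_predominant"),
    list(profile(0, 0, 0, 0, 1, 3, 1, 1, 0, 0, 0, 0), "amygdala_predominant"),
    list(profile(0, 0, 3, 2, 2, 1, 0, 0, 0, 0, 0, 0), "brainstem"),
    list(profile(3, 3, 3, 3, 3, 3, 3, 3, 3, 2, 0, 0), "diffuse_neocortical"),
    list(profile(0, 0, 2, 1, 2, 2, 1, 2, 1, 1, 0, 0), "limbic"),
    # nigral LRP without limbic/neocortical spread is brainstem, not
    # non-classifiable (which is reserved for medulla/pons/spinal-only LRP)
    list(profile(0, 0, 2, 1, 2, 0, 0, 0, 0, 0, 0, 0), "brainstem"),
    # amygdala tie with another region fails strict predominance
    list(profile(0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0), "limbic")
  )
  for (case in cases) {
    expect_equal(as.character(classify_dlb_type(case[[1]])), case[[2]],
                 info = paste(case[[1]], collapse = ","))
  }

  # thresholds are overridable through the rule table
  strict <- lrp_rules(neocortical_min = 4)
  p <- profile(3, 3, 3, 3, 3, 3, 3, 3, 3, 2, 0, 0)
  expect_equal(as.character(classify_dlb_type(p, rules = strict)), "limbic")
})

test_that("both classifiers are total and structurally concordant on the score grid", {
  # exhaustive sub-grid: all 3^12 profiles with scores in {0, 2, 4}
  grid <- as.matrix(expand.grid(rep(list(c(0, 2, 4)), 12)))
  colnames(grid) <- lrp_regions()$region
  prog <- classify_progression(grid)
  dlb <- classify_dlb_type(grid)

  # totality: exactly one label each, never NA
  expect_false(anyNA(prog))
  expect_false(anyNA(dlb))

  # brainstem type implies caudo-rostral progression unless the amygdala
  # outscores the medulla
  bs <- dlb == "brainstem"
  amy_gt_med <- grid[, "amygdala"] > grid[, "medulla"]
  expect_true(all(prog[bs] == "caudo_rostral" | amy_gt_med[bs]))

  # every amygdala-predominant profile follows the amygdala-based pattern
  expect_true(all(prog[dlb == "amygdala_predominant"] == "amygdala_based"))

  # non-classifiable (early caudo-rostral) profiles all classify caudo-rostral
  expect_true(all(prog[dlb == "non_classifiable"] == "caudo_rostral"))
})

test_that("AD and control neuropathological criteria dichotomize Braak/CERAD", {
  expect_equal(as.character(classify_nia_ri("V", "frequent")), "AD")
  expect_equal(as.character(classify_nia_ri("IV", "moderate")), "AD")
  expect_equal(as.character(classify_nia_ri("II", "frequent")), "not_AD")
  expect_equal(as.character(classify_nia_ri("VI", "sparse")), "not_AD")
  expect_equal(as.character(classify_nia_ri(NA, "moderate")), "indeterminate")

  expect_equal(as.character(classify_control_status("II", "none")), "control")
  expect_equal(as.character(classify_control_status("III", "sparse")), "not_control")
  expect_equal(as.character(classify_control_status("0", "sparse")), "control")
  expect_equal(as.character(classify_control_status(NA, "none")), "indeterminate")

  # vectorized over a cohort column
  res <- classify_nia_ri(c("V", "II"), c("frequent", "none"))
  expect_equal(as.character(res), c("AD", "not_AD"))
})
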