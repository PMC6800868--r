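test_that("archetype profiles realize the configured gradients", {
  # noiseless full-stage caudo-rostral profile is non-increasing
  cr <- archetype_profile("caudo_rostral", s = 1, noise_sd = 0)
  expect_true(all(diff(as.numeric(cr[1, ])) <= 0))

  # amygdala-based profile peaks at the amygdala
  ab <- archetype_profile("amygdala_based", s = 1, noise_sd = 0)
  expect_equal(unname(which.max(ab[1, ])), 6L)
  expect_equal(max(ab[1, ]), unname(ab[1, "amygdala"]))

  # low-stage noiseless profiles: nonzero scores confined to the peak
  # regions; round(4 * 0.05 * w) = 0 for every default weight
  for (pat in c("caudo_rostral", "amygdala_based")) {
    low <- archetype_profile(pat, s = 0.05, noise_sd = 0)
    expect_true(all(low == 0), info = pat)
  }
  # at s = 0.2 exactly the high-weight regions survive rounding
  low_cr <- archetype_profile("caudo_rostral", s = 0.2, noise_sd = 0)
  expect_true(all(low_cr[1, 1:5] == 1) && all(low_cr[1, 6:12] == 0))
  low_ab <- archetype_profile("amygdala_based", s = 0.2, noise_sd = 0)
  expect_equal(unname(which(low_ab[1, ] > 0)), c(6L, 8L))

  expect_error(archetype_profile("caudo_rostral", s = 0), "\\(0, 1\\]")
  expect_error(archetype_profile("caudo_rostral", s = 1.2), "\\(0, 1\\]")
})

test_that("pattern-conditional covariate draws match the configured rates", {
  cfg <- synthetic_config()
  set.seed(501)
  ab <- sample_covariates("amygdala_based", 1e4, cfg)
  expect_lt(abs(mean(ab$dementia == "yes") * 100 - 93), 3)

  set.seed(502)
  cr <- sample_covariates("caudo_rostral", 1e4, cfg)
  expect_lt(abs(mean(cr$apoe_e4 == "yes") * 100 - 29), 3)

  # onset ordering: amygdala-based dements earlier than caudo-rostral
  expect_lt(mean(ab$age_at_dementia_onset, na.rm = TRUE),
            mean(cr$age_at_dementia_onset, na.rm = TRUE))
  expect_true(all(ab$age_at_death >= 85))
  expect_true(all(is.na(ab$age_at_dementia_onset[ab$dementia == "no"])))

  # degenerate multinomial always draws its single bin
  cfg_deg <- synthetic_config()
  cfg_deg$covariate_tables$none$braak <- c(braak_0_II = 1, braak_III_IV = 0, braak_V_VI = 0)
  set.seed(503)
  deg <- sample_covariates("none", 200, cfg_deg)
  expect_true(all(deg$braak_stage %in% c("0", "I", "II")))

  expect_error(sample_covariates("sideways", 10, cfg), "unknown pattern")
})

test_that("generated covariates match the configured multinomials (chi-square GOF)", {
  cfg <- synthetic_config()
  set.seed(601)
  for (pat in c("none", "caudo_rostral", "amygdala_based")) {
    draws <- sample_covariates(pat, 1e4, cfg)
    bins <- cut(as.integer(draws$braak_stage), c(0, 3, 5, 7),
                labels = c("braak_0_II", "braak_III_IV", "braak_V_VI"))
    obs <- table(bins)
    p <- stats::chisq.test(obs, p = cfg$covariate_tables[[pat]]$braak)$p.value
    expect_gt(p, 0.01)
    sn_obs <- table(draws$sn_neuron_loss)
    keep <- cfg$covariate_tables[[pat]]$sn > 0
    p_sn <- stats::chisq.test(sn_obs[keep],
                              p = cfg$covariate_tables[[pat]]$sn[keep])$p.value
    expect_gt(p_sn, 0.01)
  }
})

test_that("generate_cohort is seeded, sized and proportioned as configured", {
  expect_equal(nrow(generate_cohort(synthetic_config(0), seed = 1)), 0)

  a <- generate_cohort(synthetic_config(120), seed = 9)
  b <- generate_cohort(synthetic_config(120), seed = 9)
  expect_identical(a, b)
  c2 <- generate_cohort(synthetic_config(120), seed = 10)
  expect_false(identical(a, c2))

  big <- generate_cohort(synthetic_config(1e4), seed = 77)
  prop <- table(big$true_pattern) / nrow(big)
  expect_lt(abs(prop[["none"]] - 0.60), 0.02)
  expect_lt(abs(prop[["caudo_rostral"]] - 0.27), 0.02)
  expect_lt(abs(prop[["amygdala_based"]] - 0.13), 0.02)
  expect_equal(nrow(validate_cohort(big)), 0)

  # LRP-negative subjects carry all-zero profiles
  m <- score_matrix(big)
  expect_true(all(m[big$true_pattern == "none", ] == 0))

  # saturated profiles injected on request
  sat <- generate_cohort(synthetic_config(10, n_saturated = 2), seed = 3)
  expect_equal(sum(sat$true_pattern == "undetermined"), 2)
  expect_true(all(score_matrix(sat)[sat$true_pattern == "undetermined", ] == 4))
})

test_that("rule classifier recovers the generator's true patterns", {
  # noiseless, full extent: recovery is exact
  cfg0 <- synthetic_config(300, noise_sd = 0, stage_range = c(1, 1))
  co <- classify_cohort(generate_cohort(cfg0, seed = 5))
  pos <- lrp_positive(co)
  expect_equal(mean(as.character(pos$progression_pattern) ==
                    as.character(pos$true_pattern)), 1)

  # study noise level, stage spread: recovery at least 95%
  cfg <- synthetic_config(304, noise_sd = 0.3, stage_range = c(0.2, 1))
  co <- classify_cohort(generate_cohort(cfg, seed = 5))
  pos <- lrp_positive(co)
  expect_gte(mean(as.character(pos$progression_pattern) ==
                  as.character(pos$true_pattern)), 0.95)
})

test_that("progression label of noiseless archetypes is invariant in stage", {
  for (s in c(0.2, 0.35, 0.5, 0.75, 1)) {
    expect_equal(as.character(classify_progression(
      archetype_profile("caudo_rostral", s, noise_sd = 0))), "caudo_rostral",
      info = paste("s =", s))
    expect_equal(as.character(classify_progression(
      archetype_profile("amygdala_based", s, noise_sd = 0))), "amygdala_based",
      info = paste("s =", s))
  }
})
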