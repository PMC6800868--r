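test_that("contingency tables count complete cases into the requested bins", {
  cohort <- dplyr::bind_rows(
    make_subject("a", dementia = "yes"), make_subject("b", dementia = "no"),
    make_subject("c", dementia = "yes"), make_subject("d", dementia = "yes")
  )
  cohort$group <- c("cr", "cr", "ab", "ab")
  tab <- build_contingency(cohort, "group", "dementia",
                           row_bins = list(cr = "cr", ab = "ab"),
                           col_bins = list(yes = "yes", no = "no"))
  expect_equal(unname(tab), rbind(c(1, 1), c(2, 0)))
  expect_equal(dimnames(tab), list(c("cr", "ab"), c("yes", "no")))

  # a variable that is entirely missing yields a valid zero-total table
  cohort$apoe_e4 <- factor(NA, levels = c("no", "yes"))
  tab0 <- build_contingency(cohort, "group", "apoe_e4")
  expect_equal(sum(tab0), 0)

  expect_error(
    build_contingency(cohort, "group", "dementia",
                      col_bins = list(a = c("yes", "no"), b = "no")),
    "overlapping"
  )
  expect_error(build_contingency(cohort, "group", "nope"), "no such column")

  # binning a synthetic cohort reproduces direct counting
  syn <- generate_cohort(synthetic_config(500), seed = 23)
  bins <- list(braak_0_II = c("0", "I", "II"), braak_III_IV = c("III", "IV"),
               braak_V_VI = c("V", "VI"))
  tab <- build_contingency(syn, "true_pattern", "braak_stage", col_bins = bins)
  keep <- !is.na(syn$braak_stage)
  manual <- table(droplevels(factor(syn$true_pattern[keep])),
                  cut(as.integer(syn$braak_stage[keep]), c(0, 3, 5, 7)))
  expect_equal(as.integer(tab), as.integer(manual))
})

test_that("2x2 exact test agrees with full enumeration and published values", {
  expect_equal(fisher_exact_2x2(rbind(c(1, 0), c(0, 1)))$p_two_sided, 1.0)
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))$p_two_sided, 2 / 252)

  res <- fisher_exact_2x2(rbind(c(37, 3), c(52, 31)))
  expect_equal(signif(res$p_two_sided, 4), 0.0004478)
  expect_equal(res$odds_ratio, (37 * 31) / (3 * 52))
  expect_equal(res$method, "enumeration")

  # undefined odds ratio on a zero off-diagonal product
  expect_true(is.na(fisher_exact_2x2(rbind(c(5, 0), c(3, 2)))$odds_ratio))

  expect_error(fisher_exact_2x2(rbind(c(1, 2, 3), c(4, 5, 6))), "2x2")
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(3, 1))), "non-negative")

  # random tables: equality with the binomial-coefficient oracle and with
  # the reference implementation in stats
  set.seed(91)
  for (i in 1:25) {
    m <- matrix(rpois(4, 6), 2)
    if (sum(m) == 0) m[1, 1] <- 1
    p <- fisher_exact_2x2(m)$p_two_sided
    expect_equal(p, fisher_oracle_2x2(m), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("r x c exact test enumerates margin-preserving tables correctly", {
  # consistency: identical p to the 2x2 route on 2x2 input
  for (m in list(rbind(c(37, 3), c(52, 31)), rbind(c(2, 7), c(8, 2)),
                 rbind(c(1, 0), c(0, 1)))) {
    expect_equal(fisher_exact_rxc(m)$p_two_sided,
                 fisher_exact_2x2(m)$p_two_sided, tolerance = 1e-12)
  }

  # an all-zero row carries no probability: p equals the reduced table's
  z <- rbind(c(5, 2), c(0, 0), c(3, 8))
  expect_equal(fisher_exact_rxc(z)$p_two_sided,
               fisher_exact_rxc(rbind(c(5, 2), c(3, 8)))$p_two_sided)

  # published 3-level comparison and the reference implementation
  braak <- rbind(c(34, 36, 13), c(54, 92, 34))
  res <- fisher_exact_rxc(braak)
  expect_equal(signif(res$p_two_sided, 4), 0.2306)
  expect_equal(res$p_two_sided, stats::fisher.test(braak)$p.value, tolerance = 1e-6)

  # invariance under row swap, column swap and transpose
  m <- rbind(c(3, 1, 4), c(2, 6, 1), c(0, 2, 5))
  p0 <- fisher_exact_rxc(m)$p_two_sided
  expect_equal(fisher_exact_rxc(m[c(2, 1, 3), ])$p_two_sided, p0)
  expect_equal(fisher_exact_rxc(m[, c(3, 2, 1)])$p_two_sided, p0)
  expect_equal(fisher_exact_rxc(t(m))$p_two_sided, p0)

  # degenerate margins admit a single table
  expect_equal(fisher_exact_rxc(rbind(c(4, 0), c(0, 0)))$p_two_sided, 1)

  # cap exceeded without Monte-Carlo is an error stating the cap
  expect_error(fisher_exact_rxc(braak, cap = 10), "monte_carlo")
})

test_that("Monte-Carlo p converges to the enumerated p", {
  m <- rbind(c(8, 3, 4), c(2, 7, 5))
  exact <- fisher_exact_rxc(m)$p_two_sided
  n_draws <- 4e4
  mc <- fisher_exact_rxc(m, cap = 10, monte_carlo = TRUE,
                         n_draws = n_draws, seed = 33)
  expect_equal(mc$method, "monte_carlo")
  se <- sqrt(exact * (1 - exact) / n_draws)
  expect_lt(abs(mc$p_two_sided - exact), 3 * se)
})

test_that("all exact p-values lie in (0, 1]", {
  set.seed(95)
  for (i in 1:20) {
    m <- matrix(rpois(6, 3), 2)
    if (sum(m) == 0) m[1, 1] <- 1
    p <- fisher_exact_rxc(m)$p_two_sided
    expect_true(p > 0 && p <= 1)
  }
})

test_that("two-sample t test handles standard and degenerate inputs", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  res <- two_sample_t(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  res <- two_sample_t(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 0)
  expect_true(is.infinite(res$statistic))

  res <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)

  set.seed(7)
  a <- rnorm(30); b <- rnorm(30, 1)
  expect_equal(two_sample_t(a, b)$p_value, stats::t.test(a, b)$p.value)
  expect_equal(two_sample_t(a, b, "pooled")$p_value,
               stats::t.test(a, b, var.equal = TRUE)$p.value)

  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("group-mean regression reduces to the pooled t test for two groups", {
  set.seed(8)
  vals <- c(rnorm(12), rnorm(15, 0.5))
  grp <- rep(c("a", "b"), c(12, 15))
  reg <- group_mean_regression(vals, grp)
  tt <- two_sample_t(vals[grp == "a"], vals[grp == "b"], variant = "pooled")
  expect_equal(reg$p_value, tt$p_value, tolerance = 1e-12)
  expect_equal(reg$statistic, tt$statistic^2, tolerance = 1e-12)

  # identical group means with within-group spread: F = 0, p = 1
  flat <- group_mean_regression(c(0, 1, 0, 1, 0, 1), rep(c("a", "b", "c"), each = 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_error(group_mean_regression(1:5, rep("a", 5)), "at least 2 groups")
})
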