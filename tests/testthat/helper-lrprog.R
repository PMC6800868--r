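# Shared test helpers: profile constructors and an independent brute-force
# exact-test oracle.

# length-12 profile in caudo-rostral order from a plain numeric vector
profile <- function(...) {
  x <- c(...)
  stopifnot(length(x) == 12)
  x
}

# minimal valid one-subject cohort tibble; scores default to all zero
make_subject <- function(subject_id = "S1", scores = rep(0L, 12),
                         sex = "female", age_at_death = 92,
                         dementia = "no", age_at_dementia_onset = NA_real_,
                         braak_stage = "II", cerad = "none",
                         sn_neuron_loss = "mild", apoe_e4 = "no") {
  row <- tibble::tibble(
    subject_id = subject_id, sex = sex, age_at_death = age_at_death,
    dementia = dementia, age_at_dementia_onset = age_at_dementia_onset,
    braak_stage = braak_stage, cerad = cerad,
    sn_neuron_loss = sn_neuron_loss, apoe_e4 = apoe_e4
  )
  for (i in seq_along(lrp_regions()$region)) {
    row[[lrp_regions()$region[i]]] <- as.integer(scores[i])
  }
  lrprog:::parse_cohort(dplyr::mutate(
    row, dplyr::across(dplyr::everything(), as.character)))
}

# brute-force two-sided Fisher p for a 2x2 table: enumerate every table with
# the observed margins, probability via binomial coefficients
fisher_oracle_2x2 <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- r1 + r2
  a <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  p_obs <- choose(r1, m[1, 1]) * choose(r2, c1 - m[1, 1]) / choose(n, c1)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# expected row totals of each embedded published comparison (the group-size
# denominators of the published tables)
fixture_row_totals <- list(
  dementia_amy_vs_cr = c(40, 83), dementia_amy_vs_none = c(40, 180),
  braak_amy_vs_cr = c(40, 83), braak_amy_vs_none = c(40, 180),
  braak_cr_vs_none = c(83, 180),
  cerad_amy_vs_cr = c(40, 83), cerad_amy_vs_none = c(40, 180),
  cerad_cr_vs_none = c(83, 180),
  apoe_amy_vs_cr = c(35, 78), apoe_amy_vs_none = c(35, 170),
  apoe_cr_vs_none = c(78, 170),
  spinal_cr_vs_amy = c(83, 40), sex_cr_vs_amy = c(83, 40)
)
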