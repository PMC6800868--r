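#' Default archetype gradients for the two progression patterns
#'
#' Per-region weights in [0,1] describing the relative LRP load of each
#' progression archetype along the caudo-rostral axis. The caudo-rostral
#' archetype peaks at the spinal cord and medulla and decays toward the
#' neocortex; the amygdala-based archetype peaks sharply at the amygdala and
#' decays toward both the brainstem and the neocortex. The values are
#' qualitative emulations of the published per-region density ordering, not
#' measurements, and can be overridden in [synthetic_config()].
#'
#' @return A named list of two numeric length-12 vectors
#'   (`caudo_rostral`, `amygdala_based`) in region order.
#' @export
archetype_weights <- function() {
  list(
    caudo_rostral = c(1.0, 0.95, 1.0, 0.9, 0.85, 0.6, 0.45, 0.55, 0.4, 0.3, 0.25, 0.2),
    amygdala_based = c(0.2, 0.2, 0.35, 0.3, 0.45, 1.0, 0.6, 0.8, 0.6, 0.5, 0.4, 0.3)
  )
}

# per-pattern covariate multinomials, conditioned on the published
# pattern-wise tables (no-LRP n = 180, caudo-rostral n = 83,
# amygdala-based n = 40; APOE over the genotyped subsets)
default_covariate_tables <- function() {
  list(
    none = list(
      braak = c(braak_0_II = 54, braak_III_IV = 92, braak_V_VI = 34) / 180,
      cerad = c(none = 46, sparse = 24, moderate_frequent = 110) / 180,
      apoe_e4 = 44 / 170,
      dementia = 106 / 180,
      sn = c(none = 6, mild = 115, moderate = 54, severe = 4) / 179,
      onset_mean = 87.2
    ),
    caudo_rostral = list(
      braak = c(braak_0_II = 34, braak_III_IV = 36, braak_V_VI = 13) / 83,
      cerad = c(none = 24, sparse = 9, moderate_frequent = 50) / 83,
      apoe_e4 = 24 / 78,
      dementia = 52 / 83,
      sn = c(none = 0, mild = 36, moderate = 36, severe = 11) / 83,
      onset_mean = 88.5
    ),
    amygdala_based = list(
      braak = c(braak_0_II = 2, braak_III_IV = 13, braak_V_VI = 25) / 40,
      cerad = c(none = 1, sparse = 0, moderate_frequent = 39) / 40,
      apoe_e4 = 22 / 35,
      dementia = 37 / 40,
      sn = c(none = 1, mild = 10, moderate = 25, severe = 4) / 40,
      onset_mean = 85.3
    )
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a population-based
#' autopsy series of subjects aged 85+ in which 59% have no LRP, 27% follow
#' the caudo-rostral and 13% the amygdala-based progression pattern (the
#' remaining 1% mass is assigned to the no-LRP class in place of the single
#' pattern-undetermined subject), with pattern-conditional covariate
#' distributions taken from the published group-wise tables.
#'
#' @param n_subjects Cohort size (default 304, the published series).
#' @param pattern_probs Named probabilities over `none`, `caudo_rostral`,
#'   `amygdala_based`; must sum to 1.
#' @param stage_range Range of the latent disease extent `s`; profiles are
#'   generated at `s` drawn uniformly from this interval. The default lower
#'   bound 0.2 is the smallest extent at which an archetype profile still
#'   rounds to a nonzero score.
#' @param noise_sd Gaussian noise SD on the pre-rounding score scale
#'   (default 0.3).
#' @param weights Archetype weight vectors, see [archetype_weights()].
#' @param covariate_tables Per-pattern multinomial parameters (see source of
#'   `default_covariate_tables` for the structure).
#' @param age_mean,age_sd Age-at-death distribution, normal truncated at 85
#'   (defaults 92.4 and 3.7 years).
#' @param onset_sd SD of the dementia-onset age around its pattern-specific
#'   mean (default 4 years).
#' @param n_saturated Number of additional subjects with every region scored
#'   4 (pattern-undetermined archetype; default 0).
#' @return A validated list of class `lrp_synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 304,
                             pattern_probs = c(none = 0.60,
                                               caudo_rostral = 0.27,
                                               amygdala_based = 0.13),
                             stage_range = c(0.2, 1),
                             noise_sd = 0.3,
                             weights = archetype_weights(),
                             covariate_tables = default_covariate_tables(),
                             age_mean = 92.4,
                             age_sd = 3.7,
                             onset_sd = 4,
                             n_saturated = 0) {
  stopifnot(
    n_subjects >= 0,
    length(pattern_probs) == 3,
    all(names(pattern_probs) == c("none", "caudo_rostral", "amygdala_based")),
    abs(sum(pattern_probs) - 1) < 1e-12, all(pattern_probs >= 0),
    noise_sd >= 0,
    length(stage_range) == 2, stage_range[1] > 0, stage_range[2] <= 1,
    stage_range[1] <= stage_range[2],
    age_sd > 0, onset_sd > 0, n_saturated >= 0
  )
  for (pat in names(covariate_tables)) {
    tab <- covariate_tables[[pat]]
    for (nm in c("braak", "cerad", "sn")) {
      if (abs(sum(tab[[nm]]) - 1) > 1e-12) {
        stop(sprintf("covariate table '%s/%s' does not sum to 1", pat, nm),
             call. = FALSE)
      }
    }
  }
  structure(
    list(n_subjects = n_subjects, pattern_probs = pattern_probs,
         stage_range = stage_range, noise_sd = noise_sd, weights = weights,
         covariate_tables = covariate_tables, age_mean = age_mean,
         age_sd = age_sd, onset_sd = onset_sd, n_saturated = n_saturated),
    class = "lrp_synthetic_config"
  )
}

# round half away from zero, then clamp into the 0-4 score range
round_score <- function(x) pmin(pmax(floor(abs(x) + 0.5) * sign(x), 0), 4)

#' Generate archetype severity profiles
#'
#' Realizes a profile from a progression archetype at latent extent `s`:
#' each region score is `clamp(round(4 * s * weight + noise), 0, 4)` with
#' independent Gaussian noise. Rounding is half-away-from-zero.
#'
#' @param pattern `"caudo_rostral"` or `"amygdala_based"`.
#' @param s Latent extent(s) in (0, 1]; one profile is generated per value.
#' @param noise_sd Gaussian noise SD on the pre-rounding scale.
#' @param weights Archetype weight list, see [archetype_weights()].
#' @return An integer score matrix with `length(s)` rows and the twelve
#'   region columns. Draws come from the current RNG state; seed the stream
#'   (e.g. `set.seed()`) for reproducibility.
#' @examples
#' set.seed(1)
#' archetype_profile("caudo_rostral", s = 1, noise_sd = 0)
#' @export
archetype_profile <- function(pattern = c("caudo_rostral", "amygdala_based"),
                              s, noise_sd = 0, weights = archetype_weights()) {
  pattern <- match.arg(pattern)
  if (any(s <= 0 | s > 1)) stop("latent extent s must lie in (0, 1]", call. = FALSE)
  w <- weights[[pattern]]
  stopifnot(length(w) == 12, all(w >= 0 & w <= 1))
  n <- length(s)
  base <- outer(4 * s, w)
  eps <- matrix(stats::rnorm(n * 12L, sd = noise_sd), nrow = n)
  m <- round_score(base + eps)
  storage.mode(m) <- "integer"
  colnames(m) <- lrp_region_names
  m
}

# draw one ordinal level uniformly within a coarse bin
refine_braak <- function(bin) {
  purrr::map_chr(bin, function(b) switch(b,
    braak_0_II = sample(c("0", "I", "II"), 1L),
    braak_III_IV = sample(c("III", "IV"), 1L),
    braak_V_VI = sample(c("V", "VI"), 1L)
  ))
}
refine_cerad <- function(bin) {
  purrr::map_chr(bin, function(b) switch(b,
    none = "none", sparse = "sparse",
    moderate_frequent = sample(c("moderate", "frequent"), 1L)
  ))
}

rtrunc_norm <- function(n, mean, sd, lower) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Draw covariates conditional on a progression pattern
#'
#' Samples Braak stage, CERAD score, APOE e4 carrier status, dementia
#' status, substantia nigra neuron loss, age at death (normal truncated at
#' 85) and, for subjects with dementia, dementia-onset age from the
#' pattern-conditional distributions of the configuration. With the default
#' configuration, mean onset age is lower for the amygdala-based than for
#' the caudo-rostral pattern.
#'
#' @param pattern One of `none`, `caudo_rostral`, `amygdala_based`.
#' @param n Number of subjects to draw.
#' @param config A [synthetic_config()].
#' @return A tibble of covariates with `n` rows. Uses the current RNG state.
#' @export
sample_covariates <- function(pattern, n, config = synthetic_config()) {
  if (!pattern %in% names(config$covariate_tables)) {
    stop("unknown pattern: ", pattern, call. = FALSE)
  }
  tab <- config$covariate_tables[[pattern]]
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  braak_bin <- draw(tab$braak)
  cerad_bin <- draw(tab$cerad)
  dementia <- factor(ifelse(stats::runif(n) < tab$dementia, "yes", "no"),
                     levels = c("no", "yes"))
  age <- rtrunc_norm(n, config$age_mean, config$age_sd, 85)
  onset <- rep(NA_real_, n)
  has_dem <- dementia == "yes"
  onset[has_dem] <- pmin(
    stats::rnorm(sum(has_dem), tab$onset_mean, config$onset_sd),
    age[has_dem]
  )
  tibble::tibble(
    sex = factor(ifelse(stats::runif(n) < 0.83, "female", "male"),
                 levels = c("male", "female")),
    age_at_death = round(age, 1),
    dementia = dementia,
    age_at_dementia_onset = round(onset, 1),
    braak_stage = factor(refine_braak(braak_bin), levels = braak_levels, ordered = TRUE),
    cerad = factor(refine_cerad(cerad_bin), levels = cerad_levels, ordered = TRUE),
    sn_neuron_loss = factor(draw(tab$sn), levels = sn_levels, ordered = TRUE),
    apoe_e4 = factor(ifelse(stats::runif(n) < tab$apoe_e4, "yes", "no"),
                     levels = c("no", "yes"))
  )
}

#' Generate a synthetic autopsy cohort
#'
#' Draws a cohort of subjects: each is assigned a true progression pattern
#' from `pattern_probs`; LRP-negative subjects receive an all-zero profile,
#' pattern subjects an archetype profile at a uniformly drawn latent extent
#' with Gaussian score noise, and all subjects pattern-conditional
#' covariates. The true pattern label is retained in the `true_pattern`
#' column as ground truth for recovery testing. Identical seeds give
#' identical cohorts.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed controlling all randomness.
#' @return A cohort tibble (see [read_cohort()] for the column contract)
#'   with the extra `true_pattern` column.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_subjects = 20), seed = 1)
#' dplyr::count(cohort, true_pattern)
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "lrp_synthetic_config"))
  set.seed(as.integer(seed))
  n <- config$n_subjects + config$n_saturated
  if (n == 0) {
    empty <- parse_cohort(tibble::tibble(!!!stats::setNames(
      rep(list(character()), length(c(cohort_covariate_cols, lrp_region_names))),
      c(cohort_covariate_cols, lrp_region_names))))
    empty$true_pattern <- factor(character(), levels = lrp_pattern_levels)
    return(empty)
  }
  pattern <- sample(names(config$pattern_probs), config$n_subjects,
                    replace = TRUE, prob = config$pattern_probs)
  pattern <- c(pattern, rep("undetermined", config$n_saturated))

  scores <- matrix(0L, nrow = n, ncol = 12L,
                   dimnames = list(NULL, lrp_region_names))
  for (pat in c("caudo_rostral", "amygdala_based")) {
    idx <- which(pattern == pat)
    if (length(idx) == 0) next
    s <- stats::runif(length(idx), config$stage_range[1], config$stage_range[2])
    scores[idx, ] <- archetype_profile(pat, s, config$noise_sd, config$weights)
  }
  scores[pattern == "undetermined", ] <- 4L

  # saturated profiles share the amygdala-based covariate table (the one
  # published saturated subject sat among the heavy-AD-pathology profiles)
  cov_pattern <- ifelse(pattern == "undetermined", "amygdala_based", pattern)
  parts <- purrr::imap(split(seq_len(n), cov_pattern), function(rows, pat) {
    dplyr::mutate(sample_covariates(pat, length(rows), config), .row = rows)
  })
  cov <- dplyr::select(dplyr::arrange(dplyr::bind_rows(parts), .data$.row), -".row")

  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%04d", seq_len(n))),
    cov,
    tibble::as_tibble(scores),
    tibble::tibble(true_pattern = factor(ifelse(rowSums(scores > 0) == 0, "none", pattern),
                                         levels = lrp_pattern_levels))
  )
}
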