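#' Rule thresholds for the DLB Consortium type classifier
#'
#' The consensus typing rules are realized as one explicit rule table so the
#' thresholds can be inspected and overridden. `paucity_max` is the maximum
#' score a non-amygdala region may carry in the amygdala-predominant type,
#' `neocortical_min` the neocortical score that defines the diffuse
#' neocortical type, and `sn_min` the substantia nigra involvement required
#' by the brainstem type (medulla/pons/spinal LRP alone, without nigral
#' involvement, is non-classifiable).
#'
#' @param paucity_max Maximum non-amygdala score for amygdala-predominant
#'   typing (default 1).
#' @param neocortical_min Minimum neocortical maximum for diffuse
#'   neocortical typing (default 2).
#' @param sn_min Minimum substantia nigra score for brainstem typing
#'   (default 1).
#' @return A named list of thresholds.
#' @export
lrp_rules <- function(paucity_max = 1, neocortical_min = 2, sn_min = 1) {
  stopifnot(paucity_max >= 0, neocortical_min >= 1, sn_min >= 1)
  list(paucity_max = paucity_max, neocortical_min = neocortical_min,
       sn_min = sn_min)
}

# accepts a length-12 vector, a score matrix, or a cohort tibble;
# returns a numeric matrix with NA for missing scores
as_score_matrix <- function(profiles) {
  if (is.data.frame(profiles)) return(score_matrix(profiles))
  if (is.matrix(profiles)) {
    if (ncol(profiles) != 12L) stop("score matrix must have 12 columns", call. = FALSE)
    m <- profiles
  } else {
    if (length(profiles) != 12L) stop("a profile has exactly 12 scores", call. = FALSE)
    m <- matrix(profiles, nrow = 1L)
  }
  storage.mode(m) <- "double"
  colnames(m) <- lrp_region_names
  bad <- !is.na(m) & (m < 0 | m > 4 | m != round(m))
  if (any(bad)) stop("region scores must be integers in 0-4 or missing", call. = FALSE)
  if (any(rowSums(!is.na(m)) == 0)) {
    stop("profile with all twelve scores missing", call. = FALSE)
  }
  m
}

row_max <- function(sub) do.call(pmax, c(asplit(sub, 2L), na.rm = TRUE))

block_stat <- function(m, idx, what = c("mean", "max")) {
  what <- match.arg(what)
  sub <- m[, idx, drop = FALSE]
  n_present <- rowSums(!is.na(sub))
  out <- if (what == "mean") {
    rowSums(sub, na.rm = TRUE) / n_present   # NaN when block empty
  } else {
    suppressWarnings(row_max(sub))           # -Inf when block empty
  }
  out <- as.numeric(out)
  out[n_present == 0] <- NA_real_
  out
}

#' Summarise a severity profile by anatomical block
#'
#' Computes the mean and maximum LRP score of the caudal (spinal cord to
#' substantia nigra), limbic (amygdala to cingulate) and neocortical
#' (temporal to parietal) blocks, over the non-missing regions of each block.
#' A block with no scored region yields mean 0 and max 0 with its missing
#' flag set.
#'
#' @param profiles A cohort tibble, a score matrix, or a single length-12
#'   score vector in caudo-rostral region order.
#' @return A tibble with one row per profile: block means, block maxima, the
#'   amygdala score, and `*_missing` flags for empty blocks.
#' @examples
#' block_summary(c(0, 0, 1, 0, 1, 4, 2, 3, 2, 1, 1, 0))
#' @export
block_summary <- function(profiles) {
  m <- as_score_matrix(profiles)
  out <- tibble::tibble(
    caudal_mean = block_stat(m, lrp_block_index$caudal, "mean"),
    limbic_mean = block_stat(m, lrp_block_index$limbic, "mean"),
    neocortical_mean = block_stat(m, lrp_block_index$neocortical, "mean"),
    caudal_max = block_stat(m, lrp_block_index$caudal, "max"),
    limbic_max = block_stat(m, lrp_block_index$limbic, "max"),
    neocortical_max = block_stat(m, lrp_block_index$neocortical, "max"),
    amygdala = m[, "amygdala"]
  )
  out$caudal_missing <- is.na(out$caudal_mean)
  out$limbic_missing <- is.na(out$limbic_mean)
  out$neocortical_missing <- is.na(out$neocortical_mean)
  for (col in c("caudal_mean", "limbic_mean", "neocortical_mean",
                "caudal_max", "limbic_max", "neocortical_max")) {
    out[[col]][is.na(out[[col]])] <- 0
  }
  out
}

#' Classify severity profiles into LRP progression patterns
#'
#' Systematic anatomical scoring of the whole density/distribution profile:
#' a subject whose limbic block carries on average stronger LRP than the
#' caudal block follows the amygdala-based pattern, one whose caudal block
#' dominates follows the caudo-rostral pattern. Profiles with no LRP are
#' `none`; a profile scored "very severe" (4) in every available region is
#' pattern-`undetermined`. An exact tie of the two block means is resolved
#' by the single-region comparison amygdala versus medulla, defaulting to
#' caudo-rostral (the majority pattern). Missing regions are skipped, never
#' imputed; when either comparator block is entirely missing the decision
#' falls back to the medulla-versus-amygdala comparison.
#'
#' @inheritParams block_summary
#' @return A factor with levels `none`, `caudo_rostral`, `amygdala_based`,
#'   `undetermined`; one element per profile. Every valid profile receives
#'   exactly one label.
#' @examples
#' classify_progression(c(4, 3, 4, 3, 3, 2, 1, 2, 1, 1, 0, 0)) # caudo_rostral
#' classify_progression(c(0, 0, 1, 0, 1, 4, 2, 3, 2, 1, 1, 0)) # amygdala_based
#' @export
classify_progression <- function(profiles) {
  m <- as_score_matrix(profiles)
  bs <- block_summary(m)
  all_zero <- rowSums(m > 0, na.rm = TRUE) == 0
  all_four <- rowSums(m == 4, na.rm = TRUE) == rowSums(!is.na(m))

  medulla <- m[, "medulla"]
  amygdala <- m[, "amygdala"]
  # single-score fallback comparison; missing scores count as 0
  amy_gt_med <- dplyr::coalesce(amygdala, 0) > dplyr::coalesce(medulla, 0)

  use_fallback <- bs$caudal_missing | bs$limbic_missing
  limbic_wins <- ifelse(
    use_fallback,
    amy_gt_med,
    bs$limbic_mean > bs$caudal_mean |
      (bs$limbic_mean == bs$caudal_mean & amy_gt_med)
  )

  lab <- ifelse(all_zero, "none",
         ifelse(all_four, "undetermined",
         ifelse(limbic_wins, "amygdala_based", "caudo_rostral")))
  factor(lab, levels = lrp_pattern_levels)
}

#' Classify severity profiles into DLB Consortium types
#'
#' Applies the consensus LRP typing rules in a fixed precedence order:
#' no LRP (`none`); LRP confined to the spinal cord, medulla and/or pons with
#' no nigral, limbic or neocortical involvement (`non_classifiable`, the
#' profiles the consensus scheme cannot place); amygdala scored above every
#' other region with at most mild LRP elsewhere (`amygdala_predominant`);
#' at least moderate neocortical LRP (`diffuse_neocortical`); nigral
#' involvement with at most mild limbic and no neocortical LRP
#' (`brainstem`); everything else (`limbic`). Missing regions are treated as
#' not involved.
#'
#' @inheritParams block_summary
#' @param rules Rule thresholds from [lrp_rules()].
#' @return A factor with levels `none`, `non_classifiable`, `brainstem`,
#'   `amygdala_predominant`, `limbic`, `diffuse_neocortical`.
#' @examples
#' classify_dlb_type(c(1, 0, 2, 1, 0, 0, 0, 0, 0, 0, 0, 0)) # non_classifiable
#' classify_dlb_type(c(0, 0, 0, 0, 0, 3, 0, 0, 0, 0, 0, 0)) # amygdala_predominant
#' @export
classify_dlb_type <- function(profiles, rules = lrp_rules()) {
  m <- as_score_matrix(profiles)
  m0 <- m
  m0[is.na(m0)] <- 0

  bs <- block_summary(m)
  all_zero <- rowSums(m0 > 0) == 0

  lower_brainstem <- rowSums(m0[, 1:4, drop = FALSE] > 0) > 0
  outside_lower <- rowSums(m0[, 5:12, drop = FALSE] > 0) > 0
  non_classifiable <- lower_brainstem & !outside_lower

  amy <- m0[, "amygdala"]
  other_max <- row_max(m0[, setdiff(1:12, 6L), drop = FALSE])
  amygdala_predominant <- amy > 0 & amy > other_max & other_max <= rules$paucity_max

  diffuse <- bs$neocortical_max >= rules$neocortical_min
  brainstem <- m0[, "substantia_nigra"] >= rules$sn_min &
    bs$limbic_max <= 1 & bs$neocortical_max == 0

  lab <- ifelse(all_zero, "none",
         ifelse(non_classifiable, "non_classifiable",
         ifelse(amygdala_predominant, "amygdala_predominant",
         ifelse(diffuse, "diffuse_neocortical",
         ifelse(brainstem, "brainstem", "limbic")))))
  factor(lab, levels = lrp_dlb_levels)
}

#' Classify cohort subjects with both rule engines
#'
#' Appends `dlb_type` and `progression_pattern` columns to a cohort tibble.
#'
#' @param cohort A cohort tibble with the twelve region columns.
#' @param rules Rule thresholds from [lrp_rules()].
#' @return The cohort with the two classification columns appended.
#' @export
classify_cohort <- function(cohort, rules = lrp_rules()) {
  m <- score_matrix(cohort)
  dplyr::mutate(cohort,
    dlb_type = classify_dlb_type(m, rules = rules),
    progression_pattern = classify_progression(m)
  )
}

#' Neuropathological AD status under modified NIA-RI criteria
#'
#' A subject meets the neuropathological AD definition when the CERAD
#' neuritic-plaque score is moderate or frequent and the Braak NFT stage is
#' IV-VI. A missing input yields `indeterminate`.
#'
#' @param braak Braak NFT stage: ordered factor or character with levels
#'   `0`, `I`, ..., `VI`.
#' @param cerad CERAD score: `none`, `sparse`, `moderate`, `frequent`.
#' @return A factor with levels `not_AD`, `AD`, `indeterminate`.
#' @examples
#' classify_nia_ri("V", "frequent") # AD
#' classify_nia_ri("II", "frequent") # not_AD
#' @export
classify_nia_ri <- function(braak, cerad) {
  braak <- factor(as.character(braak), levels = braak_levels, ordered = TRUE)
  cerad <- factor(as.character(cerad), levels = cerad_levels, ordered = TRUE)
  ad <- braak >= "IV" & cerad >= "moderate"
  lab <- ifelse(is.na(braak) | is.na(cerad), "indeterminate",
                ifelse(ad, "AD", "not_AD"))
  factor(lab, levels = c("not_AD", "AD", "indeterminate"))
}

#' Neuropathological control status
#'
#' Control subjects require a neuritic-plaque score of none or sparse and a
#' Braak NFT stage below III. A missing input yields `indeterminate`.
#'
#' @inheritParams classify_nia_ri
#' @return A factor with levels `not_control`, `control`, `indeterminate`.
#' @export
classify_control_status <- function(braak, cerad) {
  braak <- factor(as.character(braak), levels = braak_levels, ordered = TRUE)
  cerad <- factor(as.character(cerad), levels = cerad_levels, ordered = TRUE)
  ctrl <- braak < "III" & cerad <= "sparse"
  lab <- ifelse(is.na(braak) | is.na(cerad), "indeterminate",
                ifelse(ctrl, "control", "not_control"))
  factor(lab, levels = c("not_control", "control", "indeterminate"))
}
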