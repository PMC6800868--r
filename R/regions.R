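#' Anatomical regions scored for Lewy-related pathology
#'
#' The twelve CNS regions in fixed caudo-rostral order, together with their
#' block membership. The caudal block covers spinal cord through substantia
#' nigra (indices 1-5), the limbic block amygdala through cingulate cortex
#' (6-9), and the neocortical block temporal through parietal cortex (10-12).
#' The order is anatomical and immutable; every score matrix and profile in
#' the package uses these names in this order.
#'
#' @return A tibble with columns `index` (1-12), `region` (column name used
#'   in cohort tables) and `block` (`"caudal"`, `"limbic"` or
#'   `"neocortical"`).
#' @examples
#' lrp_regions()
#' @export
lrp_regions <- function() {
  tibble::tibble(
    index = 1:12,
    region = lrp_region_names,
    block = rep(c("caudal", "limbic", "neocortical"), times = c(5L, 4L, 3L))
  )
}

# canonical column order; used everywhere a profile is a vector or matrix
lrp_region_names <- c(
  "sacral_spinal", "thoracic_spinal", "medulla", "pons", "substantia_nigra",
  "amygdala", "ca2", "transentorhinal", "cingulate", "temporal", "frontal",
  "parietal"
)

lrp_block_index <- list(
  caudal = 1:5,
  limbic = 6:9,
  neocortical = 10:12
)

# progression pattern / DLB type level sets (factor levels, fixed order)
lrp_pattern_levels <- c("none", "caudo_rostral", "amygdala_based", "undetermined")
lrp_dlb_levels <- c(
  "none", "non_classifiable", "brainstem", "amygdala_predominant",
  "limbic", "diffuse_neocortical"
)

braak_levels <- c("0", "I", "II", "III", "IV", "V", "VI")
cerad_levels <- c("none", "sparse", "moderate", "frequent")
sn_levels <- c("none", "mild", "moderate", "severe")

#' Extract the region-score matrix from a cohort table
#'
#' @param cohort A cohort tibble containing the twelve region columns.
#' @param impute_zero Replace missing scores with 0 (required before
#'   clustering). Default `FALSE` keeps `NA`s.
#' @return An integer matrix with one row per subject and the twelve region
#'   columns in caudo-rostral order, rownames taken from `subject_id` when
#'   present.
#' @export
score_matrix <- function(cohort, impute_zero = FALSE) {
  missing_cols <- setdiff(lrp_region_names, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing region columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(as.data.frame(cohort)[, lrp_region_names, drop = FALSE])
  storage.mode(m) <- "double"
  if (impute_zero) m[is.na(m)] <- 0
  if ("subject_id" %in% names(cohort)) rownames(m) <- cohort$subject_id
  m
}

#' Keep only subjects with detectable Lewy-related pathology
#'
#' A subject is LRP-positive when at least one non-missing region score is
#' greater than zero. Subjects whose twelve scores are all zero (or missing)
#' are dropped.
#'
#' @param cohort A cohort tibble.
#' @return The filtered tibble.
#' @export
lrp_positive <- function(cohort) {
  m <- score_matrix(cohort, impute_zero = TRUE)
  cohort[rowSums(m > 0) > 0, , drop = FALSE]
}
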