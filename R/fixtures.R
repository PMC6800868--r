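#' Published contingency tables for the progression-pattern comparisons
#'
#' The count tables behind every exact test reported in the source study's
#' results: dementia status, Braak NFT stage (three bins), CERAD score (three
#' bins), APOE e4 carrier status, spinal LRP presence and sex, each
#' cross-classified against pairs of progression-pattern groups
#' (amygdala-based n = 40, caudo-rostral n = 83, no LRP n = 180; APOE tables
#' use the genotyped subsets n = 35/78/170). Tables are shipped as plain text
#' inside the package together with the published p-value and a citation
#' string, so the printed statistics can be recomputed without external data.
#'
#' @return A tibble with one row per comparison: `comparison_id`, `table`
#'   (list-column of labelled integer matrices), `printed_p` and `source`.
#' @seealso [reproduce_printed_statistics()]
#' @examples
#' fx <- lrp_printed_comparisons()
#' fx$table[[which(fx$comparison_id == "dementia_amy_vs_cr")]]
#' @export
lrp_printed_comparisons <- function() {
  path <- system.file("extdata", "printed_comparisons.csv", package = "lrprog",
                      mustWork = TRUE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tables <- purrr::pmap(raw, function(comparison_id, nrow, ncol, row_labels,
                                      col_labels, counts, ...) {
    matrix(as.integer(strsplit(counts, ";")[[1]]),
           nrow = nrow, ncol = ncol, byrow = TRUE,
           dimnames = list(strsplit(row_labels, ";")[[1]],
                           strsplit(col_labels, ";")[[1]]))
  })
  tibble::tibble(
    comparison_id = raw$comparison_id,
    table = tables,
    printed_p = raw$printed_p,
    printed_sf = as.integer(raw$printed_sf),
    source = raw$source
  )
}

#' Published cohort composition counts
#'
#' Subject counts of the source cohort (n = 304 autopsied very-elderly
#' subjects) by progression pattern and by DLB Consortium type, as printed in
#' the study's cross-classification table. One LRP-positive subject scored
#' "very severe" in every region and has an undetermined progression pattern.
#'
#' @return A list with two tibbles: `pattern` (progression-pattern counts)
#'   and `dlb_type` (DLB Consortium type counts).
#' @export
lrp_published_counts <- function() {
  list(
    pattern = tibble::tibble(
      pattern = factor(lrp_pattern_levels, levels = lrp_pattern_levels),
      n = c(180L, 83L, 40L, 1L)
    ),
    dlb_type = tibble::tibble(
      dlb_type = factor(lrp_dlb_levels, levels = lrp_dlb_levels),
      n = c(180L, 11L, 19L, 10L, 41L, 43L)
    )
  )
}
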