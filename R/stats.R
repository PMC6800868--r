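#' Cross-classify cohort subjects into a contingency table
#'
#' Counts subjects over two categorical variables (or derived labels such as
#' `progression_pattern`), optionally collapsing levels into named bins.
#' Subjects missing either variable are dropped (complete-case analysis, as
#' the varying published denominators imply). Bins must not overlap.
#'
#' @param cohort A cohort tibble.
#' @param row_var,col_var Column names (strings) of the two variables.
#' @param row_bins,col_bins Optional named lists mapping bin label to a
#'   character vector of levels, e.g.
#'   `list(braak_0_II = c("0", "I", "II"), ...)`. Levels not covered by any
#'   bin are dropped. `NULL` keeps the observed levels.
#' @return A matrix of counts with bin labels as dimnames, in the order
#'   given.
#' @examples
#' cohort <- classify_cohort(generate_cohort(synthetic_config(100), seed = 1))
#' build_contingency(cohort, "progression_pattern", "dementia")
#' @export
build_contingency <- function(cohort, row_var, col_var,
                              row_bins = NULL, col_bins = NULL) {
  for (v in c(row_var, col_var)) {
    if (!v %in% names(cohort)) stop("no such column: ", v, call. = FALSE)
  }
  bin_values <- function(x, bins, what) {
    x <- as.character(x)
    if (is.null(bins)) {
      lev <- if (is.factor(cohort[[what]])) {
        intersect(levels(cohort[[what]]), unique(x))
      } else sort(unique(stats::na.omit(x)))
      return(factor(x, levels = lev))
    }
    all_levels <- unlist(bins, use.names = FALSE)
    if (anyDuplicated(all_levels)) {
      stop("overlapping bins for ", what, ": level(s) ",
           paste(unique(all_levels[duplicated(all_levels)]), collapse = ", "),
           " appear in more than one bin", call. = FALSE)
    }
    out <- rep(NA_character_, length(x))
    for (lab in names(bins)) out[x %in% bins[[lab]]] <- lab
    factor(out, levels = names(bins))
  }
  rows <- bin_values(cohort[[row_var]], row_bins, row_var)
  cols <- bin_values(cohort[[col_var]], col_bins, col_var)
  keep <- !is.na(rows) & !is.na(cols)
  tab <- table(rows[keep], cols[keep])
  matrix(as.integer(tab), nrow = nrow(tab), ncol = ncol(tab),
         dimnames = unname(dimnames(tab)))
}

#' Two-sample t test
#'
#' Welch (default) or pooled-variance two-sample t test, returned as a tidy
#' one-row tibble. When both samples have zero variance the t statistic is
#' degenerate: the result carries `degenerate = TRUE` with `p_value = 0`
#' (different means, infinite t) or `p_value = 1` (equal means, t = 0).
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param variant `"welch"` or `"pooled"`.
#' @return A tibble: `statistic`, `df`, `p_value`, `mean_x`, `mean_y`,
#'   `degenerate`.
#' @export
two_sample_t <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    same <- mean(x) == mean(y)
    return(tibble::tibble(
      statistic = if (same) 0 else Inf * sign(mean(x) - mean(y)),
      df = NA_real_, p_value = if (same) 1 else 0,
      mean_x = mean(x), mean_y = mean(y), degenerate = TRUE
    ))
  }
  fit <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  tibble::tibble(
    statistic = unname(fit$statistic), df = unname(fit$parameter),
    p_value = fit$p.value, mean_x = mean(x), mean_y = mean(y),
    degenerate = FALSE
  )
}

#' Overall group effect by linear regression
#'
#' Least-squares fit of a continuous response on group indicators; returns
#' the overall F test for the group factor, the comparison used when more
#' than two groups are involved. With exactly two groups the p-value equals
#' that of the pooled-variance t test.
#'
#' @param values Numeric response.
#' @param groups Categorical group membership (same length as `values`).
#' @return A tibble: `statistic` (F), `df1`, `df2`, `p_value`, `n_groups`.
#' @export
group_mean_regression <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(values) <= nlevels(groups)) {
    stop("need residual degrees of freedom: more observations than groups",
         call. = FALSE)
  }
  fit <- stats::lm(values ~ groups)
  an <- stats::anova(fit)
  tibble::tibble(
    statistic = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
    p_value = an$`Pr(>F)`[1], n_groups = nlevels(groups)
  )
}

#' Recompute the published association statistics from embedded tables
#'
#' Runs the package's exact-test implementation on every embedded published
#' contingency table ([lrp_printed_comparisons()]) and compares the computed
#' p-value with the printed one at the precision the source printed
#' (agreement after rounding the computed value to the printed number of
#' significant figures).
#'
#' @return A tibble: `comparison_id`, `computed_p`, `printed_p`,
#'   `agrees_printed`, `source`.
#' @examples
#' reproduce_printed_statistics()
#' @export
reproduce_printed_statistics <- function() {
  fx <- lrp_printed_comparisons()
  res <- purrr::map_dbl(fx$table, function(tab) {
    if (nrow(tab) == 2L && ncol(tab) == 2L) {
      fisher_exact_2x2(tab)$p_two_sided
    } else {
      fisher_exact_rxc(tab)$p_two_sided
    }
  })
  tibble::tibble(
    comparison_id = fx$comparison_id,
    computed_p = res,
    printed_p = fx$printed_p,
    agrees_printed = abs(signif(res, fx$printed_sf) - fx$printed_p) <=
      fx$printed_p * 1e-8,
    source = fx$source
  )
}
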