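# Exact tests on contingency tables by full hypergeometric enumeration.
# Two-sided p-values follow the probability-mass rule: the sum of the
# probabilities, under fixed margins, of every table no more probable than
# the observed one. Ties in probability are compared with a relative
# tolerance of 1e-12 so that mathematically equal masses computed through
# different factorial groupings are treated as equal.

PROB_TOL <- 1e-12

check_table <- function(m, min_dim = 2L) {
  if (!is.matrix(m)) stop("contingency table must be a matrix", call. = FALSE)
  if (nrow(m) < min_dim || ncol(m) < min_dim) {
    stop(sprintf("contingency table must be at least %dx%d", min_dim, min_dim),
         call. = FALSE)
  }
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("contingency table entries must be non-negative integers", call. = FALSE)
  }
  if (sum(m) < 1) stop("contingency table total must be at least 1", call. = FALSE)
  invisible(m)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates the hypergeometric distribution of the top-left cell over all
#' tables with the observed margins and sums the probabilities of tables no
#' more probable than the observed one (probability-mass two-sided rule).
#' The odds ratio is the sample cross-product ratio `ad/bc`, undefined
#' (`NA`) when `b*c = 0`.
#'
#' @param m A 2x2 matrix of non-negative integer counts.
#' @return A tibble of class `lrp_exact_test` row: `p_two_sided`,
#'   `odds_ratio`, `method` (`"enumeration"`) and `n_tables_enumerated`.
#' @examples
#' fisher_exact_2x2(rbind(c(37, 3), c(52, 31)))
#' @export
fisher_exact_2x2 <- function(m) {
  check_table(m)
  if (nrow(m) != 2L || ncol(m) != 2L) stop("table must be 2x2", call. = FALSE)
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + PROB_TOL)]))
  or <- if (m[1, 2] * m[2, 1] == 0) NA_real_ else
    (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  new_exact_result(p, or, "enumeration", length(support))
}

new_exact_result <- function(p, or, method, n_tables) {
  structure(
    tibble::tibble(p_two_sided = p, odds_ratio = or, method = method,
                   n_tables_enumerated = as.integer(n_tables)),
    class = c("lrp_exact_test", class(tibble::tibble()))
  )
}

# log multivariate-hypergeometric probability of a full r x c table with
# the given margins: log[ prod(r_i!) prod(c_j!) / (N! prod(n_ij!)) ]
log_table_prob <- function(cells, row_sums, col_sums) {
  sum(lgamma(row_sums + 1)) + sum(lgamma(col_sums + 1)) -
    lgamma(sum(row_sums) + 1) - sum(lgamma(cells + 1))
}

# visit every non-negative integer r x c table with the given margins,
# calling fun(cells) for each; returns the number of tables visited.
# Enumeration is row-major: each row is a bounded composition of its total.
enumerate_margin_tables <- function(row_sums, col_sums, fun, cap = Inf) {
  r <- length(row_sums)
  count <- 0L
  cells <- numeric(0)
  recurse_row <- function(i, col_left, acc) {
    if (i == r) {
      # last row forced by remaining column totals
      count <<- count + 1L
      if (count > cap) stop("enumeration_cap", call. = FALSE)
      fun(c(acc, col_left))
      return(invisible())
    }
    compositions(row_sums[i], col_left, function(row) {
      recurse_row(i + 1L, col_left - row, c(acc, row))
    })
    invisible()
  }
  recurse_row(1L, col_sums, numeric(0))
  count
}

# all vectors x >= 0 with sum(x) = total and x <= bound (elementwise)
compositions <- function(total, bound, fun) {
  k <- length(bound)
  rec <- function(j, left, acc) {
    if (j == k) {
      if (left <= bound[k]) fun(c(acc, left))
      return(invisible())
    }
    hi <- min(left, bound[j])
    lo <- max(0, left - sum(bound[(j + 1):k]))
    if (hi < lo) return(invisible())
    for (v in lo:hi) rec(j + 1L, left - v, c(acc, v))
    invisible()
  }
  rec(1L, total, numeric(0))
}

#' Two-sided Fisher exact test for an r x c table
#'
#' Enumerates every non-negative integer table with the observed row and
#' column margins, computes each table's multivariate hypergeometric
#' probability, and sums the probabilities of tables no more probable than
#' the observed one. On a 2x2 input this reduces to the same p-value as
#' [fisher_exact_2x2()]. When the number of margin-preserving tables exceeds
#' `cap`, the exact sum is replaced (if `monte_carlo = TRUE`) by a
#' Monte-Carlo estimate over `n_draws` margin-preserving tables drawn with
#' Patefield's algorithm (`stats::r2dtable`); otherwise an error states the
#' cap.
#'
#' @param m An r x c matrix of non-negative integer counts (r, c >= 2).
#' @param cap Maximum number of tables to enumerate (default 1e8).
#' @param monte_carlo Fall back to Monte-Carlo estimation when the cap is
#'   exceeded.
#' @param n_draws Number of Monte-Carlo draws (default 1e6).
#' @param seed Optional seed for the Monte-Carlo fallback.
#' @return A tibble row as in [fisher_exact_2x2()]; `odds_ratio` is `NA`
#'   for tables larger than 2x2 and `method` records which route was used.
#' @examples
#' fisher_exact_rxc(rbind(c(34, 36, 13), c(54, 92, 34)))
#' @export
fisher_exact_rxc <- function(m, cap = 1e8, monte_carlo = FALSE,
                             n_draws = 1e6, seed = NULL) {
  check_table(m)
  row_sums <- rowSums(m); col_sums <- colSums(m)
  # rows or columns with zero total admit a single (all-zero) fill and do
  # not change any table's probability; drop them before enumerating
  keep_r <- row_sums > 0; keep_c <- col_sums > 0
  if (!all(keep_r) || !all(keep_c)) {
    m2 <- m[keep_r, keep_c, drop = FALSE]
    if (nrow(m2) < 2L || ncol(m2) < 2L) {
      # degenerate margins: the observed table is the only one possible
      return(new_exact_result(1, NA_real_, "enumeration", 1L))
    }
    res <- fisher_exact_rxc(m2, cap = cap, monte_carlo = monte_carlo,
                            n_draws = n_draws, seed = seed)
    return(res)
  }

  log_obs <- log_table_prob(as.vector(t(m)), row_sums, col_sums)
  log_tol <- log1p(PROB_TOL)
  or <- if (nrow(m) == 2L && ncol(m) == 2L && m[1, 2] * m[2, 1] > 0) {
    (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  } else NA_real_

  mass <- 0
  count <- tryCatch({
    enumerate_margin_tables(row_sums, col_sums, function(cells) {
      lp <- log_table_prob(cells, row_sums, col_sums)
      if (lp <= log_obs + log_tol) mass <<- mass + exp(lp)
    }, cap = cap)
  }, error = function(e) {
    if (conditionMessage(e) == "enumeration_cap") NA_integer_ else stop(e)
  })

  if (!is.na(count)) {
    return(new_exact_result(min(1, mass), or, "enumeration", count))
  }
  if (!monte_carlo) {
    stop(sprintf("more than %g margin-preserving tables; rerun with monte_carlo = TRUE",
                 cap), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  draws <- stats::r2dtable(n_draws, row_sums, col_sums)
  lps <- vapply(draws, function(d) log_table_prob(as.vector(d), row_sums, col_sums),
                numeric(1))
  p <- mean(lps <= log_obs + log_tol)
  new_exact_result(max(p, 1 / n_draws), or, "monte_carlo", as.integer(n_draws))
}

#' @export
print.lrp_exact_test <- function(x, ...) {
  cat(sprintf("Fisher exact test (%s, %d tables): p = %.6g",
              x$method, x$n_tables_enumerated, x$p_two_sided))
  if (!is.na(x$odds_ratio)) cat(sprintf(", OR = %.4g", x$odds_ratio))
  cat("\n")
  invisible(x)
}
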