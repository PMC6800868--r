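#' K-means clustering of LRP severity profiles
#'
#' Clusters subjects by their twelve-region severity profiles with Lloyd's
#' algorithm under unweighted Euclidean distance on the raw 0-4 scores (all
#' coordinates share one scale, so no standardization), k-means++ seeding,
#' and best-of-`n_init` restarts by within-cluster sum of squares. Missing
#' scores must be imputed to 0 beforehand ([score_matrix()] with
#' `impute_zero = TRUE` does this); only LRP-positive subjects are normally
#' clustered.
#'
#' @param profiles A cohort tibble or a complete numeric matrix with twelve
#'   columns (one row per subject).
#' @param k Number of clusters (at most the number of distinct profiles).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param n_init Number of k-means++ restarts (default 25).
#' @return An object of class `lrp_kmeans`: a list with `k`, `centers`
#'   (k x 12 matrix), `cluster` (integer assignments, named by subject when
#'   available), `wss` (total within-cluster sum of squares), `sizes`,
#'   `n_init` and `seed`.
#' @examples
#' cohort <- lrp_positive(generate_cohort(synthetic_config(100), seed = 1))
#' fit <- fit_lrp_kmeans(cohort, k = 2, seed = 1)
#' glance(fit)
#' @export
fit_lrp_kmeans <- function(profiles, k, seed = 1, n_init = 25) {
  x <- if (is.data.frame(profiles)) score_matrix(profiles, impute_zero = TRUE) else profiles
  if (!is.matrix(x) || ncol(x) != 12L) stop("profiles must have 12 columns", call. = FALSE)
  if (nrow(x) == 0) stop("no profiles to cluster", call. = FALSE)
  if (anyNA(x)) stop("profiles must be complete; impute missing scores first", call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop(sprintf("k = %d exceeds the %d distinct profiles", k, n_distinct),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- kmeanspp_centers(x, k)
    # Lloyd can abandon a restart when a cluster empties; skip that restart
    fit <- tryCatch(
      suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = 300, algorithm = "Lloyd")
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) {
    best <- stats::kmeans(x, centers = k, iter.max = 300, nstart = n_init)
  }
  structure(
    list(k = k, centers = unname(best$centers),
         cluster = stats::setNames(best$cluster, rownames(x)),
         wss = best$tot.withinss, sizes = best$size,
         n_init = n_init, seed = seed),
    class = "lrp_kmeans"
  )
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2L, centers[1, ])^2)
  for (j in 2:k) {
    # points coinciding with a chosen center have d2 = 0 and are never
    # redrawn, so the k centers are distinct whenever k <= n distinct points
    centers[j, ] <- x[sample.int(n, 1L, prob = d2), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' @export
print.lrp_kmeans <- function(x, ...) {
  cat(sprintf("K-means fit: k = %d, n = %d, total WSS = %.3f\n",
              x$k, length(x$cluster), x$wss))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.lrp_kmeans <- function(x, ...) {
  centers <- tibble::as_tibble(x$centers, .name_repair = ~lrp_region_names)
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$k), size = x$sizes),
    centers
  )
}

#' @exportS3Method generics::glance
glance.lrp_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$cluster), wss = x$wss,
                 n_init = x$n_init, seed = x$seed)
}

#' Within-cluster sum-of-squares curve across k
#'
#' Fits [fit_lrp_kmeans()] for k = 1..`k_max` and records the total
#' within-cluster sum of squares of each fit, the input of elbow-based model
#' selection.
#'
#' @inheritParams fit_lrp_kmeans
#' @param k_max Largest k to fit (capped at the number of distinct
#'   profiles).
#' @return A tibble of class `lrp_wss_curve` with columns `k` and `wss`.
#' @export
wss_curve <- function(profiles, k_max = 10, seed = 1, n_init = 25) {
  x <- if (is.data.frame(profiles)) score_matrix(profiles, impute_zero = TRUE) else profiles
  k_max <- min(k_max, nrow(unique(x)))
  out <- purrr::map_dfr(seq_len(k_max), function(k) {
    glance(fit_lrp_kmeans(x, k, seed = seed + k, n_init = n_init))[, c("k", "wss")]
  })
  structure(out, class = c("lrp_wss_curve", class(out)))
}

#' Select k by the elbow rule
#'
#' Formalizes the elbow criterion as the point of maximum perpendicular
#' distance from the WSS curve to the chord joining its endpoints (a
#' Kneedle-style rule). Ties resolve to the smaller k.
#'
#' @param curve A tibble with columns `k` (strictly increasing) and `wss`,
#'   with at least 3 entries.
#' @return The selected integer k.
#' @examples
#' select_k_elbow(tibble::tibble(k = 1:5, wss = c(100, 20, 18, 17, 16)))
#' @export
select_k_elbow <- function(curve) {
  stopifnot(all(c("k", "wss") %in% names(curve)))
  k <- curve$k; w <- curve$wss
  if (length(k) < 3) stop("elbow selection needs at least 3 (k, wss) points", call. = FALSE)
  if (any(diff(k) <= 0)) stop("k values must be strictly increasing", call. = FALSE)
  n <- length(k)
  dk <- k[n] - k[1]; dw <- w[n] - w[1]
  # perpendicular distance of (k_i, w_i) to the endpoint chord
  dist <- abs(dk * (w - w[1]) - dw * (k - k[1])) / sqrt(dk^2 + dw^2)
  k[which.max(dist)]
}

#' Map K-means clusters to progression patterns
#'
#' Rounds each centroid per coordinate to the nearest integer score
#' (half away from zero, clamped to 0-4) and labels it with
#' [classify_progression()], yielding an automatic analogue of reading each
#' cluster's mean profile off a plot. The saturated all-4 centroid maps to
#' `undetermined`.
#'
#' @param model An `lrp_kmeans` fit.
#' @return A tibble: `cluster`, `pattern` (factor), plus the rounded
#'   centroid scores.
#' @export
map_cluster_to_pattern <- function(model) {
  stopifnot(inherits(model, "lrp_kmeans"))
  rounded <- matrix(as.integer(round_score(model$centers)), nrow = model$k,
                    dimnames = list(NULL, lrp_region_names))
  tibble::tibble(
    cluster = seq_len(model$k),
    pattern = classify_progression(rounded)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(rounded))
}

#' Concordance between rule-based and cluster-derived pattern labels
#'
#' The fraction of subjects whose cluster's mapped pattern equals their
#' rule-based pattern. Subjects in a pattern-ambiguous (`undetermined`)
#' cluster count as concordant only when their rule label is also
#' `undetermined`.
#'
#' @param rule_labels Rule-based patterns, named by subject id (or unnamed,
#'   in subject order).
#' @param model An `lrp_kmeans` fit of the same subjects.
#' @param mapping Optional precomputed [map_cluster_to_pattern()] result.
#' @return Concordance in [0, 1].
#' @export
concordance <- function(rule_labels, model, mapping = map_cluster_to_pattern(model)) {
  cl <- model$cluster
  if (!is.null(names(rule_labels)) && !is.null(names(cl))) {
    if (!setequal(names(rule_labels), names(cl))) {
      stop("rule labels and cluster assignments cover different subjects", call. = FALSE)
    }
    rule_labels <- rule_labels[names(cl)]
  } else if (length(rule_labels) != length(cl)) {
    stop("rule labels and cluster assignments differ in length", call. = FALSE)
  }
  mapped <- mapping$pattern[cl]
  mean(as.character(mapped) == as.character(rule_labels))
}
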