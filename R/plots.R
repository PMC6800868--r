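#' Plot mean severity profiles per cluster
#'
#' One line per cluster centroid along the caudo-rostral region axis, the
#' standard way cluster solutions of regional severity profiles are read.
#'
#' @param object An `lrp_kmeans` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.lrp_kmeans <- function(object, ...) {
  centers <- tidy(object) |>
    tidyr::pivot_longer(dplyr::all_of(lrp_region_names),
                        names_to = "region", values_to = "score") |>
    dplyr::mutate(region = factor(.data$region, levels = lrp_region_names))
  ggplot2::ggplot(centers,
                  ggplot2::aes(x = .data$region, y = .data$score,
                               group = factor(.data$cluster),
                               colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 4)) +
    ggplot2::labs(x = NULL, y = "LRP score", colour = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
ggplot2::autoplot

#' Plot a within-cluster sum-of-squares curve
#'
#' The WSS against k, with the elbow chosen by [select_k_elbow()] marked.
#'
#' @param object An `lrp_wss_curve` tibble from [wss_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lrp_wss_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k", y = "within-cluster SS") +
    ggplot2::theme_minimal()
  if (nrow(object) >= 3) {
    p <- p + ggplot2::geom_vline(xintercept = select_k_elbow(object),
                                 linetype = "dashed")
  }
  p
}

#' Per-region severity summary of a cohort
#'
#' Mean region score per progression pattern along the caudo-rostral axis,
#' mirroring how the two archetype gradients are displayed.
#'
#' @param cohort A classified cohort tibble (with `progression_pattern`).
#' @return A ggplot object.
#' @export
plot_region_profiles <- function(cohort) {
  stopifnot("progression_pattern" %in% names(cohort))
  long <- cohort |>
    dplyr::filter(.data$progression_pattern %in% c("caudo_rostral", "amygdala_based")) |>
    tidyr::pivot_longer(dplyr::all_of(lrp_region_names),
                        names_to = "region", values_to = "score") |>
    dplyr::mutate(region = factor(.data$region, levels = lrp_region_names)) |>
    dplyr::group_by(.data$progression_pattern, .data$region) |>
    dplyr::summarise(mean_score = mean(.data$score, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region, y = .data$mean_score,
                                     fill = .data$progression_pattern)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean LRP score", fill = "pattern") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
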