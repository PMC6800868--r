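#' Run the full analysis pipeline
#'
#' End-to-end orchestration: simulate (or accept) a cohort, classify every
#' subject with both rule engines, cluster the LRP-positive subjects, select
#' k by the elbow rule, map clusters to progression patterns, measure
#' rule-versus-cluster concordance, and run the association tests of the
#' study design (dementia, Braak, CERAD, APOE e4 against progression
#' pattern). Deterministic given `seed`.
#'
#' @param config A [synthetic_config()], used when `cohort` is `NULL`.
#' @param cohort Optionally, an existing cohort tibble (as from
#'   [read_cohort()]); when supplied, `config` is ignored for generation.
#' @param seed Integer seed for cohort generation and clustering.
#' @param k Fixed number of clusters; `NULL` (default) selects k via
#'   [select_k_elbow()] over `1..k_max`.
#' @param k_max Largest k scanned for the elbow.
#' @param n_init K-means restarts per fit.
#' @param out_dir Optional directory; when given, the cohort, assignments,
#'   WSS curve, statistics and a plain-text report are written there.
#' @param verbose Log stage progress to standard error.
#' @return An object of class `lrp_report`: a list with `cohort`
#'   (classified tibble), `pattern_counts`, `dlb_counts`, `crosstab`
#'   (DLB type x progression pattern), `cluster` (the `lrp_kmeans` fit or
#'   `NULL` for an LRP-free cohort), `wss` curve, `selected_k`, `mapping`,
#'   `concordance`, `stats_table` and `provenance`.
#' @export
run_lrp_pipeline <- function(config = synthetic_config(), cohort = NULL,
                             seed = 1, k = NULL, k_max = 10, n_init = 25,
                             out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))

  if (is.null(cohort)) {
    say("stage simulate: n = %d, seed = %d", config$n_subjects, seed)
    cohort <- generate_cohort(config, seed = seed)
  }
  say("stage classify: %d subjects", nrow(cohort))
  cohort <- classify_cohort(cohort)

  pattern_counts <- dplyr::count(cohort, .data$progression_pattern,
                                 name = "n", .drop = FALSE)
  dlb_counts <- dplyr::count(cohort, .data$dlb_type, name = "n", .drop = FALSE)
  crosstab <- table(cohort$dlb_type, cohort$progression_pattern)

  positive <- lrp_positive(cohort)
  fit <- NULL; curve <- NULL; mapping <- NULL
  selected_k <- NA_integer_; conc <- NA_real_
  if (nrow(positive) >= 3) {
    say("stage cluster: %d LRP-positive subjects, k_max = %d", nrow(positive), k_max)
    curve <- wss_curve(positive, k_max = k_max, seed = seed, n_init = n_init)
    selected_k <- if (is.null(k)) {
      if (nrow(curve) >= 3) select_k_elbow(curve) else nrow(curve)
    } else k
    fit <- fit_lrp_kmeans(positive, k = selected_k, seed = seed, n_init = n_init)
    mapping <- map_cluster_to_pattern(fit)
    rule_labels <- stats::setNames(positive$progression_pattern, positive$subject_id)
    conc <- concordance(rule_labels, fit, mapping)
  }

  say("stage stats")
  stats_table <- cohort_association_tests(cohort)

  report <- structure(
    list(
      cohort = cohort,
      pattern_counts = pattern_counts,
      dlb_counts = dlb_counts,
      crosstab = crosstab,
      cluster = fit,
      wss = curve,
      selected_k = selected_k,
      mapping = mapping,
      concordance = conc,
      stats_table = stats_table,
      provenance = list(
        seed = seed,
        n_subjects = nrow(cohort),
        config_hash = rlang::hash(config),
        package_version = as.character(utils::packageVersion("lrprog")),
        r_version = as.character(getRversion())
      )
    ),
    class = "lrp_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# the association comparisons of the study design, run pattern-pairwise on
# whatever cohort is supplied
cohort_association_tests <- function(cohort) {
  braak_bins <- list(braak_0_II = c("0", "I", "II"),
                     braak_III_IV = c("III", "IV"),
                     braak_V_VI = c("V", "VI"))
  cerad_bins <- list(cerad_none = "none", cerad_sparse = "sparse",
                     cerad_mod_freq = c("moderate", "frequent"))
  pairs <- list(
    c("amygdala_based", "caudo_rostral"),
    c("amygdala_based", "none"),
    c("caudo_rostral", "none")
  )
  comparisons <- purrr::map(pairs, function(pair) {
    sub <- cohort[as.character(cohort$progression_pattern) %in% pair, , drop = FALSE]
    sub$group <- factor(as.character(sub$progression_pattern), levels = pair)
    vars <- list(
      dementia = list(var = "dementia", bins = list(yes = "yes", no = "no")),
      braak = list(var = "braak_stage", bins = braak_bins),
      cerad = list(var = "cerad", bins = cerad_bins),
      apoe = list(var = "apoe_e4", bins = list(yes = "yes", no = "no"))
    )
    purrr::imap_dfr(vars, function(v, nm) {
      tab <- build_contingency(sub, "group", v$var, col_bins = v$bins)
      if (nrow(tab) < 2 || ncol(tab) < 2 || any(rowSums(tab) == 0) || sum(tab) == 0) {
        return(tibble::tibble(comparison = paste0(nm, "_", pair[1], "_vs_", pair[2]),
                              p = NA_real_, n = sum(tab)))
      }
      res <- if (all(dim(tab) == 2L)) fisher_exact_2x2(tab) else fisher_exact_rxc(tab)
      tibble::tibble(comparison = paste0(nm, "_", pair[1], "_vs_", pair[2]),
                     p = res$p_two_sided, n = sum(tab))
    })
  })
  dplyr::bind_rows(comparisons)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(report$cohort, file.path(out_dir, "cohort_classified.csv"))
  if (!is.null(report$cluster)) {
    readr::write_csv(
      tibble::tibble(
        subject_id = names(report$cluster$cluster),
        cluster = unname(report$cluster$cluster),
        mapped_pattern = as.character(report$mapping$pattern[report$cluster$cluster])
      ),
      file.path(out_dir, "cluster_assignments.csv")
    )
    readr::write_csv(report$wss, file.path(out_dir, "wss_curve.csv"))
  }
  readr::write_csv(report$stats_table, file.path(out_dir, "association_tests.csv"))
  summary_path <- file.path(out_dir, "report.txt")
  con <- file(summary_path, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(out_dir)
}

#' @export
print.lrp_report <- function(x, ...) {
  cat("LRP progression-pattern pipeline report\n")
  cat(sprintf("  subjects: %d (seed %s, config %s)\n",
              x$provenance$n_subjects, x$provenance$seed, x$provenance$config_hash))
  cat("  progression patterns:\n")
  for (i in seq_len(nrow(x$pattern_counts))) {
    cat(sprintf("    %-16s %d\n",
                as.character(x$pattern_counts$progression_pattern[i]),
                x$pattern_counts$n[i]))
  }
  cat("  DLB Consortium types:\n")
  for (i in seq_len(nrow(x$dlb_counts))) {
    cat(sprintf("    %-20s %d\n",
                as.character(x$dlb_counts$dlb_type[i]), x$dlb_counts$n[i]))
  }
  if (!is.null(x$cluster)) {
    cat(sprintf("  K-means: k = %d, WSS = %.2f, concordance with rules = %.3f\n",
                x$selected_k, x$cluster$wss, x$concordance))
  }
  if (nrow(x$stats_table) > 0) {
    cat("  association tests:\n")
    for (i in seq_len(nrow(x$stats_table))) {
      cat(sprintf("    %-38s p = %s (n = %d)\n", x$stats_table$comparison[i],
                  format(x$stats_table$p[i], digits = 4), x$stats_table$n[i]))
    }
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.lrp_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$provenance$n_subjects,
    n_lrp_positive = sum(x$pattern_counts$n[x$pattern_counts$progression_pattern != "none"]),
    selected_k = x$selected_k,
    concordance = x$concordance,
    seed = x$provenance$seed
  )
}
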