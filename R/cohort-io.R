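#' Read a cohort table
#'
#' Reads a delimited text file with one row per autopsied subject: identifier,
#' demographics, AD-pathology and genetic covariates, then the twelve regional
#' LRP severity scores (0 = none, 1 = mild, 2 = moderate, 3 = severe,
#' 4 = very severe) in caudo-rostral order. The delimiter (comma or tab) is
#' auto-detected from the header line; empty cells become missing values.
#'
#' @param path Path to a CSV or TSV cohort file.
#' @param dialect `"auto"` (default), `"csv"` or `"tsv"`.
#' @return A cohort tibble with typed columns: `sex`, `dementia`, `apoe_e4`
#'   as factors, `braak_stage`, `cerad`, `sn_neuron_loss` as ordered factors,
#'   ages numeric, region scores integer. Row order is preserved.
#' @details Required columns, in any order: `subject_id`, `sex`,
#'   `age_at_death`, `dementia`, `age_at_dementia_onset`, `braak_stage`,
#'   `cerad`, `sn_neuron_loss`, `apoe_e4`, plus the twelve region columns
#'   named as in [lrp_regions()]. Unknown columns, non-integer scores and
#'   scores outside 0-4 are errors that name the offending row and column.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- switch(dialect,
    csv = ",",
    tsv = "\t",
    auto = if (grepl("\t", header)) "\t" else ","
  )
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = "",
    progress = FALSE,
    show_col_types = FALSE
  )
  parse_cohort(raw)
}

cohort_covariate_cols <- c(
  "subject_id", "sex", "age_at_death", "dementia", "age_at_dementia_onset",
  "braak_stage", "cerad", "sn_neuron_loss", "apoe_e4"
)

# character tibble -> typed cohort tibble, with row/column error reporting
parse_cohort <- function(raw) {
  expected <- c(cohort_covariate_cols, lrp_region_names)
  extras <- c("true_pattern", "dlb_type", "progression_pattern", "notes")
  unknown <- setdiff(names(raw), c(expected, extras))
  if (length(unknown) > 0) {
    stop("unknown column(s) in cohort file: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(expected, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  parse_enum <- function(x, levels, col, ordered = FALSE) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop(sprintf("invalid value '%s' in column %s, row %d (expected one of: %s)",
                   x[which(bad)[1]], col, which(bad)[1],
                   paste(levels, collapse = ", ")), call. = FALSE)
    }
    factor(x, levels = levels, ordered = ordered)
  }
  parse_score <- function(x, col) {
    num <- suppressWarnings(as.numeric(x))
    bad_num <- !is.na(x) & is.na(num)
    if (any(bad_num)) {
      stop(sprintf("non-numeric score '%s' in column %s, row %d",
                   x[which(bad_num)[1]], col, which(bad_num)[1]), call. = FALSE)
    }
    frac <- !is.na(num) & num != round(num)
    if (any(frac)) {
      stop(sprintf("non-integer score '%s' in column %s, row %d",
                   x[which(frac)[1]], col, which(frac)[1]), call. = FALSE)
    }
    oob <- !is.na(num) & (num < 0 | num > 4)
    if (any(oob)) {
      stop(sprintf("score %s outside 0-4 in column %s, row %d",
                   x[which(oob)[1]], col, which(oob)[1]), call. = FALSE)
    }
    as.integer(num)
  }

  out <- tibble::tibble(
    subject_id = as.character(raw$subject_id),
    sex = parse_enum(raw$sex, c("male", "female"), "sex"),
    age_at_death = suppressWarnings(as.numeric(raw$age_at_death)),
    dementia = parse_enum(raw$dementia, c("no", "yes"), "dementia"),
    age_at_dementia_onset = suppressWarnings(as.numeric(raw$age_at_dementia_onset)),
    braak_stage = parse_enum(raw$braak_stage, braak_levels, "braak_stage", ordered = TRUE),
    cerad = parse_enum(raw$cerad, cerad_levels, "cerad", ordered = TRUE),
    sn_neuron_loss = parse_enum(raw$sn_neuron_loss, sn_levels, "sn_neuron_loss", ordered = TRUE),
    apoe_e4 = parse_enum(raw$apoe_e4, c("no", "yes"), "apoe_e4")
  )
  for (r in lrp_region_names) out[[r]] <- parse_score(raw[[r]], r)
  for (col in c("true_pattern", "progression_pattern")) {
    if (col %in% names(raw)) {
      out[[col]] <- parse_enum(raw[[col]], lrp_pattern_levels, col)
    }
  }
  if ("dlb_type" %in% names(raw)) {
    out$dlb_type <- parse_enum(raw$dlb_type, lrp_dlb_levels, "dlb_type")
  }
  if ("notes" %in% names(raw)) out$notes <- as.character(raw$notes)
  out
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: writes the cohort as delimited text with empty
#' cells for missing values, so that a write-then-read round trip reproduces
#' the records field by field.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  out <- dplyr::mutate(cohort, dplyr::across(dplyr::where(is.factor), as.character))
  readr::write_delim(out, path, delim = if (dialect == "csv") "," else "\t", na = "")
  invisible(path)
}

#' Aggregate spinal-cord sub-site scores to the two analysed spinal regions
#'
#' LRP is scored at four spinal sub-sites (sacral posterior root entry, sacral
#' anterior horn, central canal adjacent to the sacral cord, and the thoracic
#' intermediolateral horn) but analysed as two regions. The sacral region
#' score is the maximum over the three sacral sub-sites so that any detectable
#' sacral LRP is retained; the thoracic region score is the intermediolateral
#' horn score. Missing sub-sites are ignored; when all sub-sites of a region
#' are missing the aggregated score is missing (not an error).
#'
#' @param subsites A data frame (or tibble) with columns
#'   `sacral_posterior_root`, `sacral_anterior_horn`, `sacral_central_canal`,
#'   `thoracic_intermediolateral`, each an integer 0-4 or `NA`.
#' @return A tibble with columns `sacral_spinal` and `thoracic_spinal`.
#' @examples
#' aggregate_spinal_subsites(data.frame(
#'   sacral_posterior_root = 2, sacral_anterior_horn = 0,
#'   sacral_central_canal = 1, thoracic_intermediolateral = 3
#' ))
#' @export
aggregate_spinal_subsites <- function(subsites) {
  need <- c("sacral_posterior_root", "sacral_anterior_horn",
            "sacral_central_canal", "thoracic_intermediolateral")
  missing_cols <- setdiff(need, names(subsites))
  if (length(missing_cols) > 0) {
    stop("missing sub-site column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    x <- subsites[[col]]
    if (any(!is.na(x) & (x < 0 | x > 4 | x != round(x)))) {
      stop("sub-site scores must be integers in 0-4 (column ", col, ")",
           call. = FALSE)
    }
  }
  sac <- as.matrix(subsites[, need[1:3], drop = FALSE])
  sacral <- apply(sac, 1L, function(r) if (all(is.na(r))) NA_integer_ else as.integer(max(r, na.rm = TRUE)))
  tibble::tibble(
    sacral_spinal = sacral,
    thoracic_spinal = as.integer(subsites[[need[4]]])
  )
}

#' List invariant violations in a cohort table
#'
#' Checks every subject row against the record invariants: region scores are
#' integers in 0-4, a profile must have at least one non-missing score,
#' dementia-onset age is only present for subjects with dementia and never
#' exceeds age at death, and age at death is at least 85 (the cohort design
#' samples the very elderly). Violations are returned as data, not raised.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `subject_id`, `row`, `field` and `rule`;
#'   zero rows when every record is valid.
#' @export
validate_cohort <- function(cohort) {
  viol <- list()
  add <- function(rows, field, rule) {
    if (length(rows) == 0) return()
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      subject_id = as.character(cohort$subject_id[rows]),
      row = as.integer(rows), field = field, rule = rule
    )
  }
  m <- score_matrix(cohort)
  add(which(rowSums(!is.na(m)) == 0), "profile",
      "all twelve region scores missing; profile must have at least one score")
  bad_score <- which(apply(m, 1L, function(r) any(!is.na(r) & (r < 0 | r > 4 | r != round(r)))))
  add(bad_score, "profile", "region scores must be integers in 0-4")
  onset <- cohort$age_at_dementia_onset
  add(which(!is.na(onset) & !is.na(cohort$dementia) & cohort$dementia == "no"),
      "age_at_dementia_onset", "onset age present but dementia = no")
  add(which(!is.na(onset) & !is.na(cohort$age_at_death) & onset > cohort$age_at_death),
      "age_at_dementia_onset", "onset age exceeds age at death")
  add(which(!is.na(cohort$age_at_death) & cohort$age_at_death < 85),
      "age_at_death", "age at death below 85")
  if (length(viol) == 0) {
    return(tibble::tibble(subject_id = character(), row = integer(),
                          field = character(), rule = character()))
  }
  dplyr::arrange(dplyr::bind_rows(viol), .data$row)
}

#' @rdname validate_cohort
#' @param record A one-row cohort tibble (a single subject record).
#' @export
validate_record <- function(record) {
  stopifnot(nrow(record) == 1L)
  validate_cohort(record)
}
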