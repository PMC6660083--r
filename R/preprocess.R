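#' Read a cohort intensity matrix and pathway annotation
#'
#' The cohort CSV must have a `sample_id` column, a `group` column with
#' values `case`/`control`, and one numeric column per metabolite. The
#' annotation CSV has columns `metabolite_id,pathway`. Metabolites missing
#' from the annotation are assigned pathway `"unassigned"` with a warning.
#'
#' @param matrix_path path to the cohort CSV.
#' @param annotation_path optional path to the annotation CSV.
#' @return a list with elements `cohort` (tibble: `sample_id`, `group`,
#'   metabolite columns) and `annotation` (tibble: `metabolite_id`,
#'   `pathway`; `NULL` when no annotation was given).
#' @export
read_cohort <- function(matrix_path, annotation_path = NULL) {
  cohort <- readr::read_csv(matrix_path, show_col_types = FALSE,
                            progress = FALSE)
  cohort <- validate_cohort(cohort)
  annotation <- NULL
  if (!is.null(annotation_path)) {
    annotation <- readr::read_csv(annotation_path, show_col_types = FALSE,
                                  progress = FALSE)
    annotation <- validate_annotation(annotation, metabolite_ids(cohort))
  }
  list(cohort = cohort, annotation = annotation)
}

validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  if (!all(ID_COLS %in% names(cohort))) {
    stop_format("cohort table must have 'sample_id' and 'group' columns")
  }
  if (anyDuplicated(cohort$sample_id) > 0) {
    stop_format("duplicate sample_id: %s",
                paste(unique(cohort$sample_id[duplicated(cohort$sample_id)]),
                      collapse = ", "))
  }
  mets <- metabolite_ids(cohort)
  if (anyDuplicated(mets) > 0) stop_format("duplicate metabolite columns")
  extra <- setdiff(unique(as.character(cohort$group)), GROUP_LEVELS)
  if (length(extra) > 0) {
    stop_format("group column must only contain 'case'/'control' (found: %s)",
                paste(extra, collapse = ", "))
  }
  for (m in mets) {
    col <- cohort[[m]]
    if (is.character(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(parsed))
      if (length(bad) > 0) {
        stop_format("non-numeric intensity at row %d, column '%s' ('%s')",
                    bad[1], m, col[bad[1]])
      }
      cohort[[m]] <- parsed
    } else if (!is.numeric(col)) {
      stop_format("column '%s' is not numeric", m)
    }
  }
  cohort$sample_id <- as.character(cohort$sample_id)
  cohort$group <- as.character(cohort$group)
  cohort
}

validate_annotation <- function(annotation, mets) {
  annotation <- tibble::as_tibble(annotation)
  if (!all(c("metabolite_id", "pathway") %in% names(annotation))) {
    stop_format("annotation must have columns 'metabolite_id' and 'pathway'")
  }
  if (anyDuplicated(annotation$metabolite_id) > 0) {
    stop_format("metabolite annotated more than once: %s",
                paste(unique(annotation$metabolite_id[
                  duplicated(annotation$metabolite_id)]), collapse = ", "))
  }
  missing <- setdiff(mets, annotation$metabolite_id)
  if (length(missing) > 0) {
    warn(sprintf("%d metabolite(s) absent from annotation assigned pathway 'unassigned'",
                 length(missing)))
    annotation <- dplyr::bind_rows(
      annotation,
      tibble::tibble(metabolite_id = missing, pathway = "unassigned")
    )
  }
  annotation
}

#' Write a cohort matrix (and optional annotation) to CSV
#'
#' Values are written with shortest round-trip precision, so a
#' write/[read_cohort()] cycle reproduces intensities exactly.
#'
#' @param cohort cohort tibble.
#' @param matrix_path output CSV path.
#' @param annotation optional annotation tibble.
#' @param annotation_path output path for the annotation.
#' @return `matrix_path`, invisibly.
#' @export
write_cohort <- function(cohort, matrix_path, annotation = NULL,
                         annotation_path = NULL) {
  readr::write_csv(cohort, matrix_path, progress = FALSE)
  if (!is.null(annotation) && !is.null(annotation_path)) {
    readr::write_csv(annotation, annotation_path, progress = FALSE)
  }
  invisible(matrix_path)
}

#' Log-transform raw intensities
#'
#' Natural log of `value + pseudocount`. By default a pseudocount of 1 is
#' applied only when zeros are present; otherwise 0. Missing values stay
#' missing.
#'
#' @param cohort cohort tibble with non-negative intensities.
#' @param pseudocount positive offset added before taking logs, or `NULL`
#'   for the default rule.
#' @return the cohort tibble with log-scale metabolite columns.
#' @export
log_transform <- function(cohort, pseudocount = NULL) {
  m <- met_matrix(cohort)
  if (any(m < 0, na.rm = TRUE)) {
    stop_input("intensities must be non-negative before log transformation")
  }
  if (is.null(pseudocount)) {
    pseudocount <- if (any(m == 0, na.rm = TRUE)) 1 else 0
  } else if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop_input("pseudocount must be a positive number")
  }
  if (pseudocount == 0 && any(m == 0, na.rm = TRUE)) {
    stop_input("zero intensities require a positive pseudocount")
  }
  cohort[metabolite_ids(cohort)] <- as.data.frame(log(m + pseudocount))
  cohort
}

#' Control-referenced Z-scores
#'
#' Scales every sample (cases and controls alike) by the control group's
#' per-metabolite mean and sample standard deviation:
#' `z = (x - mean_control) / sd_control`. Metabolites missing in more than
#' `max_missing` of samples, or with zero control SD, are dropped with a
#' warning. Missing values are excluded pairwise from the control mean/SD.
#'
#' @param cohort cohort tibble (typically log-transformed).
#' @param max_missing maximum tolerated fraction of missing values per
#'   metabolite (default 0.2).
#' @return a Z-score tibble with the same shape; the control reference is
#'   attached as attribute `"control_stats"` (tibble: `metabolite_id`,
#'   `mean`, `sd`).
#' @export
zscore_against_controls <- function(cohort, max_missing = 0.2) {
  ind <- require_both_classes(cohort$group)
  if (sum(!ind) < 2) {
    stop_input("at least 2 control samples are required to compute Z-scores")
  }
  m <- met_matrix(cohort)

  frac_missing <- colMeans(is.na(m))
  drop_missing <- frac_missing > max_missing
  if (any(drop_missing)) {
    warn(sprintf("dropping %d metabolite(s) missing in > %.0f%% of samples",
                 sum(drop_missing), 100 * max_missing))
    m <- m[, !drop_missing, drop = FALSE]
  }

  ctrl <- m[!ind, , drop = FALSE]
  mu <- colMeans(ctrl, na.rm = TRUE)
  sd <- apply(ctrl, 2, stats::sd, na.rm = TRUE)
  zero_sd <- !is.finite(sd) | sd == 0
  if (any(zero_sd)) {
    warn(sprintf("dropping %d metabolite(s) with zero control SD: %s",
                 sum(zero_sd),
                 paste(utils::head(colnames(m)[zero_sd], 5), collapse = ", ")))
    m <- m[, !zero_sd, drop = FALSE]
    mu <- mu[!zero_sd]
    sd <- sd[!zero_sd]
  }
  if (ncol(m) == 0) stop_input("no metabolites left after filtering")

  z <- sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
  out <- dplyr::bind_cols(cohort[ID_COLS], tibble::as_tibble(z))
  attr(out, "control_stats") <- tibble::tibble(
    metabolite_id = colnames(m), mean = unname(mu), sd = unname(sd)
  )
  out
}

#' Control reference statistics of a Z-score tibble
#'
#' @param z a tibble produced by [zscore_against_controls()].
#' @return tibble with `metabolite_id`, `mean`, `sd`.
#' @export
control_stats <- function(z) {
  cs <- attr(z, "control_stats")
  if (is.null(cs)) stop_input("no control_stats attribute; not a Z-score tibble?")
  cs
}
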