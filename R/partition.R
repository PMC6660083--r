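#' Partition extreme metabolites into diagnostic vs individualized
#'
#' For each subject, every metabolite with `|Z| >= z_cut` is an
#' abnormality. It is *diagnostic* when the metabolite's cohort-level VIP is
#' at least `vip_threshold` and the subject's Z sign matches the
#' cohort-level direction from the screen; otherwise it is *individualized*
#' (extreme only in that subject, or discordant with the shared signature).
#' Case and control profiles are both computed but summarized separately.
#'
#' @param z Z-score tibble.
#' @param screen a [screen_metabolites()] tibble over the same metabolites.
#' @param z_cut absolute Z threshold (default 2).
#' @param vip_threshold VIP threshold for the diagnostic label (default
#'   1.5, inclusive).
#' @return a list with `per_subject` (tibble: `sample_id`, `group`,
#'   `diagnostic_count`, `individualized_count`, `total_abnormal`), `flags`
#'   (long tibble of flagged subject x metabolite pairs with the assigned
#'   class), and `summary` (per-group mean +/- SE of the three counts).
#' @export
partition_abnormalities <- function(z, screen, z_cut = 2,
                                    vip_threshold = 1.5) {
  x <- met_matrix(z)
  if (!setequal(colnames(x), screen$metabolite_id)) {
    stop_input("screen and Z-score matrix cover different metabolites")
  }
  ord <- match(colnames(x), screen$metabolite_id)
  vip <- screen$vip[ord]
  dir_up <- screen$direction[ord] == "up"

  flags <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    zi <- x[i, ]
    abn <- which(abs(zi) >= z_cut)
    if (length(abn) == 0) return(NULL)
    concordant <- (zi[abn] > 0) == dir_up[abn]
    diagnostic <- vip[abn] >= vip_threshold & concordant
    tibble::tibble(
      sample_id = z$sample_id[i],
      group = z$group[i],
      metabolite_id = colnames(x)[abn],
      z = unname(zi[abn]),
      class = ifelse(diagnostic, "diagnostic", "individualized")
    )
  })

  per_subject <- tibble::tibble(sample_id = z$sample_id, group = z$group) %>%
    dplyr::left_join(
      flags %>%
        dplyr::count(.data$sample_id, .data$class) %>%
        tidyr::pivot_wider(names_from = "class", values_from = "n",
                           values_fill = 0L),
      by = "sample_id"
    )
  for (col in c("diagnostic", "individualized")) {
    if (!col %in% names(per_subject)) per_subject[[col]] <- 0L
    per_subject[[col]][is.na(per_subject[[col]])] <- 0L
  }
  per_subject <- per_subject %>%
    dplyr::rename(diagnostic_count = "diagnostic",
                  individualized_count = "individualized") %>%
    dplyr::mutate(total_abnormal = .data$diagnostic_count +
                    .data$individualized_count)

  se <- function(v) stats::sd(v) / sqrt(length(v))
  summary <- per_subject %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      n_subjects = dplyr::n(),
      mean_diagnostic = mean(.data$diagnostic_count),
      se_diagnostic = se(.data$diagnostic_count),
      mean_individualized = mean(.data$individualized_count),
      se_individualized = se(.data$individualized_count),
      mean_total = mean(.data$total_abnormal),
      se_total = se(.data$total_abnormal),
      diagnostic_fraction = sum(.data$diagnostic_count) /
        max(1, sum(.data$total_abnormal)),
      .groups = "drop"
    )
  list(per_subject = per_subject, flags = flags, summary = summary)
}
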