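#' Expected pathway hits among the top k metabolites
#'
#' Under proportional sampling, a pathway with `n_pathway` of `n_total`
#' measured metabolites expects `(n_pathway / n_total) * k` hits in a
#' selection of size `k`. Returned at full precision; report tables round
#' half-up to 1 decimal.
#'
#' @param n_pathway metabolites measured in the pathway.
#' @param n_total total measured metabolites.
#' @param k size of the selection.
#' @return expected hit count (numeric).
#' @examples
#' expected_hits(18, 358, 30) # displays as 1.5
#' @export
expected_hits <- function(n_pathway, n_total, k) {
  if (any(n_total <= 0) || any(k <= 0)) {
    stop_input("n_total and k must be positive")
  }
  if (any(n_pathway <= 0) || any(n_pathway > n_total)) {
    stop_input("n_pathway must be in 1..n_total")
  }
  (n_pathway / n_total) * k
}

#' Fold enrichment of observed over expected hits
#'
#' @param observed observed hit count.
#' @param expected expected hit count (unrounded), must be positive.
#' @return observed / expected.
#' @examples
#' fold_enrichment(4, expected_hits(18, 358, 30)) # displays as 2.7
#' @export
fold_enrichment <- function(observed, expected) {
  if (!is.numeric(expected) || expected <= 0) {
    stop_input("expected must be positive")
  }
  if (observed < 0) stop_input("observed must be non-negative")
  observed / expected
}

#' Pathway metabolic-impact table
#'
#' Aggregates the metabolite screen into per-pathway statistics: the top `k`
#' significant metabolites (ranked by VIP) are assigned to pathways; each
#' pathway's impact is the sum of its members' VIP scores, its impact
#' fraction is that sum over the total across hit pathways, and observed
#' hits are compared with proportional expectation as fold enrichment.
#' Up/down counts come from the screen directions.
#'
#' @param screen a [screen_metabolites()] tibble.
#' @param annotation annotation tibble (`metabolite_id`, `pathway`).
#' @param k number of top significant metabolites to aggregate (default
#'   30); when fewer are significant, all are used with a warning.
#' @param all_pathways keep pathways with zero observed hits (default
#'   `FALSE`, matching the reported-table convention; the full export sets
#'   this `TRUE`).
#' @return tibble sorted by impact descending: `pathway`, `n_measured`,
#'   `proportion`, `expected_hits`, `observed_hits`, `fold_enrichment`,
#'   `impact`, `impact_fraction`, `n_increased`, `n_decreased`.
#' @export
build_impact_table <- function(screen, annotation, k = 30,
                               all_pathways = FALSE) {
  if (k <= 0) stop_input("k must be positive")
  unannotated <- setdiff(screen$metabolite_id, annotation$metabolite_id)
  if (length(unannotated) > 0) {
    warn(sprintf("%d screened metabolite(s) lack annotation; assigned 'unassigned'",
                 length(unannotated)))
    annotation <- dplyr::bind_rows(
      annotation,
      tibble::tibble(metabolite_id = unannotated, pathway = "unassigned")
    )
  }
  n_total <- nrow(screen)
  sig <- screen %>%
    dplyr::filter(.data$significant) %>%
    dplyr::arrange(dplyr::desc(.data$vip), .data$p_value, .data$metabolite_id)
  if (nrow(sig) < k) {
    warn(sprintf("only %d significant metabolites available (k = %d); using all",
                 nrow(sig), k))
    k_used <- nrow(sig)
  } else {
    k_used <- k
  }
  top <- utils::head(sig, k_used) %>%
    dplyr::left_join(annotation, by = "metabolite_id")

  sizes <- annotation %>%
    dplyr::filter(.data$metabolite_id %in% screen$metabolite_id) %>%
    dplyr::count(.data$pathway, name = "n_measured")

  hits <- top %>%
    dplyr::group_by(.data$pathway) %>%
    dplyr::summarise(
      observed_hits = dplyr::n(),
      impact = sum(.data$vip),
      n_increased = sum(.data$direction == "up"),
      n_decreased = sum(.data$direction == "down"),
      .groups = "drop"
    )
  total_impact <- sum(hits$impact)

  out <- sizes %>%
    dplyr::left_join(hits, by = "pathway") %>%
    dplyr::mutate(
      observed_hits = dplyr::coalesce(.data$observed_hits, 0L),
      impact = dplyr::coalesce(.data$impact, 0),
      n_increased = dplyr::coalesce(.data$n_increased, 0L),
      n_decreased = dplyr::coalesce(.data$n_decreased, 0L),
      proportion = .data$n_measured / n_total,
      expected_hits = expected_hits(.data$n_measured, n_total, k_used),
      fold_enrichment = .data$observed_hits / .data$expected_hits,
      impact_fraction = if (total_impact > 0) .data$impact / total_impact else 0
    ) %>%
    dplyr::select("pathway", "n_measured", "proportion", "expected_hits",
                  "observed_hits", "fold_enrichment", "impact",
                  "impact_fraction", "n_increased", "n_decreased") %>%
    dplyr::arrange(dplyr::desc(.data$impact), .data$pathway)
  if (!all_pathways) out <- dplyr::filter(out, .data$observed_hits > 0)
  attr(out, "k") <- k_used
  out
}

#' Display-rounded pathway impact table
#'
#' Renders a [build_impact_table()] result with the conventional report
#' rounding: proportions to 2 decimals, expected hits, fold enrichment and
#' impact to 1 decimal (round half-up), and impact fraction as a whole
#' percentage.
#'
#' @param impact a [build_impact_table()] tibble.
#' @return tibble with rounded display columns.
#' @export
impact_table_display <- function(impact) {
  impact %>%
    dplyr::mutate(
      proportion = round_half_up(.data$proportion, 2),
      expected_hits = round_half_up(.data$expected_hits, 1),
      fold_enrichment = round_half_up(.data$fold_enrichment, 1),
      impact = round_half_up(.data$impact, 1),
      impact_fraction = sprintf("%d%%",
                                round_half_up(100 * .data$impact_fraction))
    )
}
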