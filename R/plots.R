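#' Plot PLS-DA scores
#'
#' Scatter of the first two component scores, colored by group.
#'
#' @param object a [fit_plsda()] object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot plsda_fit
#' @export
autoplot.plsda_fit <- function(object, ...) {
  df <- augment(object)
  if (object$n_components < 2) {
    df$comp_2 <- 0
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$comp_1, .data$comp_2,
                                   color = .data$group)) +
    ggplot2::geom_point(size = 2.5, alpha = 0.85) +
    ggplot2::stat_ellipse(level = 0.95, linetype = 2, na.rm = TRUE) +
    ggplot2::labs(x = "Component 1", y = "Component 2", color = NULL,
                  title = "PLS-DA scores") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the pathway impact table
#'
#' Horizontal bars of summed VIP impact per hit pathway, annotated with the
#' impact fraction.
#'
#' @param impact a [build_impact_table()] tibble.
#' @return a ggplot.
#' @export
plot_pathway_impact <- function(impact) {
  df <- impact %>%
    dplyr::mutate(pathway = stats::reorder(.data$pathway, .data$impact),
                  label = sprintf("%d%%",
                                  round_half_up(100 * .data$impact_fraction)))
  ggplot2::ggplot(df, ggplot2::aes(.data$impact, .data$pathway)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.15,
                       size = 3) +
    ggplot2::expand_limits(x = max(df$impact) * 1.12) +
    ggplot2::labs(x = "Impact (summed VIP)", y = NULL,
                  title = "Pathway metabolic impact") +
    ggplot2::theme_minimal()
}

#' Plot the top VIP-ranked metabolites
#'
#' @param screen a [screen_metabolites()] tibble.
#' @param top_n number of metabolites shown (default 25).
#' @return a ggplot.
#' @export
plot_vip_ranking <- function(screen, top_n = 25) {
  df <- utils::head(screen, top_n) %>%
    dplyr::mutate(metabolite_id = stats::reorder(.data$metabolite_id,
                                                 .data$vip))
  ggplot2::ggplot(df, ggplot2::aes(.data$vip, .data$metabolite_id,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#d66a6a", down = "#6a8bd6")) +
    ggplot2::labs(x = "VIP score", y = NULL, fill = "Direction",
                  title = sprintf("Top %d metabolites by VIP", nrow(df))) +
    ggplot2::theme_minimal()
}

#' Plot per-metabolite diagnosis correlations
#'
#' @param correlations a [diagnosis_correlations()] tibble.
#' @param top_n number of metabolites shown (default 25).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a ggplot.
#' @export
plot_diagnosis_correlations <- function(correlations, top_n = 25,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  col <- if (method == "pearson") "pearson_r" else "spearman_rho"
  df <- correlations %>%
    dplyr::arrange(dplyr::desc(abs(.data[[col]]))) %>%
    utils::head(top_n) %>%
    dplyr::mutate(
      metabolite_id = stats::reorder(.data$metabolite_id,
                                     abs(.data[[col]])),
      direction = ifelse(.data[[col]] >= 0, "up", "down")
    )
  ggplot2::ggplot(df, ggplot2::aes(.data[[col]], .data$metabolite_id,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#e8a0bf", down = "#9bb8e8")) +
    ggplot2::labs(x = sprintf("%s correlation with diagnosis",
                              if (method == "pearson") "Pearson"
                              else "Spearman"),
                  y = NULL, fill = NULL,
                  title = "Metabolites most correlated with diagnosis") +
    ggplot2::theme_minimal()
}

#' Plot a PCA scree curve
#'
#' Individual and cumulative variance fractions by component.
#'
#' @param scree a [pca_scree()] tibble.
#' @param max_components components shown (default 15).
#' @return a ggplot.
#' @export
plot_scree <- function(scree, max_components = 15) {
  df <- utils::head(scree, max_components) %>%
    tidyr::pivot_longer(c("proportion", "cumulative"),
                        names_to = "series", values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$fraction,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(
      values = c(proportion = "#4878b0", cumulative = "#52a05a"),
      labels = c(proportion = "individual", cumulative = "cumulative")
    ) +
    ggplot2::labs(x = "Principal component", y = "Variance fraction",
                  color = NULL, title = "PCA scree") +
    ggplot2::theme_minimal()
}

#' Plot the abnormality partition
#'
#' Per-subject stacked counts of diagnostic vs individualized extreme
#' metabolites.
#'
#' @param partition output of [partition_abnormalities()].
#' @param group which subjects to show (default `"case"`).
#' @return a ggplot.
#' @export
plot_abnormality_partition <- function(partition, group = "case") {
  df <- partition$per_subject %>%
    dplyr::filter(.data$group == !!group) %>%
    tidyr::pivot_longer(c("diagnostic_count", "individualized_count"),
                        names_to = "class", values_to = "count") %>%
    dplyr::mutate(class = sub("_count$", "", .data$class))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(diagnostic = "#4878b0",
                                          individualized = "#e0c24a")) +
    ggplot2::labs(x = NULL, y = "Extreme metabolites (|Z| ≥ cut)",
                  fill = NULL,
                  title = "Diagnostic vs individualized abnormalities") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
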