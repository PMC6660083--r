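#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a PLS-DA fit
#'
#' One row per metabolite per component with the weight and X-loading, plus
#' the VIP score over all components.
#'
#' @param x a [fit_plsda()] object.
#' @param ... unused.
#' @return a tibble: `metabolite_id`, `component`, `weight`, `loading`,
#'   `vip`.
#' @method tidy plsda_fit
#' @export
tidy.plsda_fit <- function(x, ...) {
  vip <- vip_scores(x)
  purrr::map_dfr(seq_len(x$n_components), function(a) {
    tibble::tibble(
      metabolite_id = x$metabolite_ids,
      component = a,
      weight = x$weights[, a],
      loading = x$x_loadings[, a]
    )
  }) %>%
    dplyr::left_join(vip, by = "metabolite_id")
}

#' Glance at a PLS-DA fit
#'
#' @param x a [fit_plsda()] object.
#' @param ... unused.
#' @return one-row tibble: `n_samples`, `n_metabolites`, `n_components`,
#'   `y_variance_explained`.
#' @method glance plsda_fit
#' @export
glance.plsda_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$sample_ids),
    n_metabolites = length(x$metabolite_ids),
    n_components = x$n_components,
    y_variance_explained = sum(x$ssy) / x$total_y_ss
  )
}

#' Per-sample scores of a PLS-DA fit
#'
#' @param x a [fit_plsda()] object.
#' @param ... unused.
#' @return tibble: `sample_id`, `group`, one `comp_<a>` column per
#'   component.
#' @method augment plsda_fit
#' @export
augment.plsda_fit <- function(x, ...) {
  scores <- tibble::as_tibble(x$scores, .name_repair = "minimal")
  names(scores) <- paste0("comp_", seq_len(ncol(scores)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = x$sample_ids, group = x$labels),
    scores
  )
}

#' Glance at a panel evaluation
#'
#' @param x a `panel_eval` row from [evaluate_panel()].
#' @param ... unused.
#' @return one-row tibble with the headline metrics.
#' @method glance panel_eval
#' @export
glance.panel_eval <- function(x, ...) {
  tibble::tibble(
    n_members = x$n_members,
    auroc = x$auroc,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    accuracy = x$accuracy,
    rdcv = x$rdcv,
    permutation_p = x$permutation_p
  )
}
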