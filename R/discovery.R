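#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis via sequential NIPALS PLS1
#' components with X deflation. The binary response is coded 0/1
#' (control/case) and centered; X columns are mean-centered (Z-score input
#' is already on a common scale, so no further scaling is applied). Weight
#' vectors have unit norm and score vectors are mutually orthogonal.
#'
#' @param z Z-score (or cohort) tibble with `sample_id`, `group` and
#'   metabolite columns; both classes must be present.
#' @param n_components number of components (default 2); must not exceed
#'   `min(n_samples - 1, n_metabolites)`.
#' @return an object of class `plsda_fit`: list with `weights` (p x A, unit
#'   columns), `scores` (n x A), `x_loadings`, `y_loadings`, `ssy`
#'   (explained response sum of squares per component), `total_y_ss`,
#'   `metabolite_ids`, `sample_ids`, `labels`, `n_components`.
#' @export
fit_plsda <- function(z, n_components = 2) {
  ind <- require_both_classes(z$group)
  x <- met_matrix(z)
  if (anyNA(x)) stop_input("PLS-DA input must not contain missing values")
  n <- nrow(x)
  p <- ncol(x)
  if (n_components < 1 || n_components > min(n - 1, p)) {
    stop_input("n_components must be in 1..min(n_samples - 1, n_metabolites)")
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  y <- as.numeric(ind)
  yc <- y - mean(y)
  total_y_ss <- sum(yc^2)

  a_max <- n_components
  w_mat <- matrix(0, p, a_max)
  t_mat <- matrix(0, n, a_max)
  p_mat <- matrix(0, p, a_max)
  b_vec <- numeric(a_max)
  ssy <- numeric(a_max)

  xd <- xc
  yd <- yc
  fitted_comps <- 0L
  for (a in seq_len(a_max)) {
    w <- crossprod(xd, yd)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_a <- drop(xd %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- crossprod(xd, t_a)[, 1] / tt
    b_a <- sum(t_a * yd) / tt
    w_mat[, a] <- w
    t_mat[, a] <- t_a
    p_mat[, a] <- p_a
    b_vec[a] <- b_a
    ssy[a] <- b_a^2 * tt
    xd <- xd - tcrossprod(t_a, p_a)
    yd <- yd - b_a * t_a
    fitted_comps <- a
  }
  if (fitted_comps == 0L) stop_input("no PLS component could be extracted")
  keep <- seq_len(fitted_comps)
  structure(
    list(
      weights = w_mat[, keep, drop = FALSE],
      scores = t_mat[, keep, drop = FALSE],
      x_loadings = p_mat[, keep, drop = FALSE],
      y_loadings = b_vec[keep],
      ssy = ssy[keep],
      total_y_ss = total_y_ss,
      x_means = attr(xc, "scaled:center"),
      metabolite_ids = colnames(x),
      sample_ids = z$sample_id,
      labels = z$group,
      n_components = fitted_comps
    ),
    class = "plsda_fit"
  )
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat(sprintf(
    "PLS-DA fit: %d samples x %d metabolites, %d component(s)\n",
    length(x$sample_ids), length(x$metabolite_ids), x$n_components))
  cat(sprintf("  Y variance explained: %.1f%%\n",
              100 * sum(x$ssy) / x$total_y_ss))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' The standard VIP score over all fitted components:
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with unit-norm
#' weight vectors `w_a` and per-component explained response sum of squares
#' `SSY_a`. Mean squared VIP is exactly 1, so `sum(VIP^2) = p`.
#'
#' @param model a [fit_plsda()] object.
#' @return tibble with `metabolite_id`, `vip`, sorted as in the model.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_fit"))
  if (sum(model$ssy) <= 0) {
    stop_input("model explains no response variance; VIP undefined")
  }
  p <- length(model$metabolite_ids)
  w2 <- model$weights^2
  vip <- sqrt(p * drop(w2 %*% model$ssy) / sum(model$ssy))
  tibble::tibble(metabolite_id = model$metabolite_ids, vip = vip)
}

#' Screen metabolites by VIP and Mann-Whitney U
#'
#' Applies the joint significance rule: a metabolite is significant when its
#' VIP exceeds `vip_threshold` (default 1.5) and its two-sided Mann-Whitney
#' U p-value is at most `p_threshold` (default 0.05). Direction is the sign
#' of the mean case Z-score. Rows are ranked by VIP descending, ties broken
#' by smaller p, then metabolite ID.
#'
#' @param z Z-score tibble.
#' @param model optional [fit_plsda()] object; fitted with `n_components`
#'   components when omitted.
#' @param n_components components for the internal fit when `model` is
#'   `NULL`.
#' @param vip_threshold,p_threshold joint rule thresholds.
#' @return tibble: `metabolite_id`, `vip`, `u_statistic`, `p_value`,
#'   `mean_case_z`, `direction` (`"up"`/`"down"`), `significant`, `rank`.
#' @export
screen_metabolites <- function(z, model = NULL, n_components = 2,
                               vip_threshold = 1.5, p_threshold = 0.05) {
  ind <- require_both_classes(z$group)
  if (is.null(model)) model <- fit_plsda(z, n_components = n_components)
  x <- met_matrix(z)
  if (!identical(colnames(x), model$metabolite_ids)) {
    stop_input("model and Z-score matrix have different metabolite axes")
  }
  u <- purrr::map_dfr(seq_len(ncol(x)), function(j) {
    mann_whitney_u(x[ind, j], x[!ind, j])
  })
  mean_case_z <- colMeans(x[ind, , drop = FALSE])
  vip_scores(model) %>%
    dplyr::mutate(
      u_statistic = u$statistic,
      p_value = u$p_value,
      mean_case_z = unname(mean_case_z),
      direction = ifelse(mean_case_z >= 0, "up", "down"),
      significant = .data$vip > vip_threshold & .data$p_value <= p_threshold
    ) %>%
    dplyr::arrange(dplyr::desc(.data$vip), .data$p_value,
                   .data$metabolite_id) %>%
    dplyr::mutate(rank = dplyr::row_number())
}

#' Per-metabolite correlation with diagnosis
#'
#' Point-biserial Pearson r and Spearman rank rho between each metabolite's
#' Z-scores and the case indicator (case = 1, control = 0). Constant
#' metabolites get correlation 0 and `constant = TRUE`.
#'
#' @param z Z-score tibble with both classes present.
#' @return tibble: `metabolite_id`, `pearson_r`, `spearman_rho`, `constant`,
#'   `pearson_rank`, `spearman_rank` (ranks by absolute correlation).
#' @export
diagnosis_correlations <- function(z) {
  ind <- require_both_classes(z$group)
  x <- met_matrix(z)
  y <- as.numeric(ind)
  const <- apply(x, 2, function(col) stats::sd(col) == 0)
  r <- suppressWarnings(as.vector(stats::cor(x, y)))
  rho <- suppressWarnings(as.vector(stats::cor(apply(x, 2, rank), rank(y))))
  r[const] <- 0
  rho[const] <- 0
  tibble::tibble(
    metabolite_id = colnames(x),
    pearson_r = r,
    spearman_rho = rho,
    constant = unname(const)
  ) %>%
    dplyr::mutate(
      pearson_rank = rank(-abs(.data$pearson_r), ties.method = "first"),
      spearman_rank = rank(-abs(.data$spearman_rho), ties.method = "first")
    )
}

#' Random-forest importance ranking of metabolites
#'
#' Permutation importance from a seeded probability forest; deterministic
#' given the seed (single-threaded).
#'
#' @param z Z-score tibble.
#' @param seed integer seed.
#' @param num_trees number of trees (default 500).
#' @param mtry features per split; default `floor(sqrt(p))`.
#' @return tibble: `metabolite_id`, `importance`, `rank`.
#' @export
rf_rank <- function(z, seed = 1L, num_trees = 500, mtry = NULL) {
  require_both_classes(z$group)
  x <- met_matrix(z)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
  df <- as.data.frame(x, check.names = FALSE)
  fit <- ranger::ranger(
    x = df, y = factor(z$group, levels = GROUP_LEVELS),
    num.trees = num_trees, mtry = mtry,
    importance = "permutation",
    seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance
  tibble::tibble(metabolite_id = names(imp), importance = unname(imp)) %>%
    dplyr::arrange(dplyr::desc(.data$importance), .data$metabolite_id) %>%
    dplyr::mutate(rank = dplyr::row_number())
}

#' Group shift test for a metabolite family
#'
#' Tests whether a family of related metabolites (for example all
#' acyl-carnitines) is shifted as a group even when no member is
#' individually significant: member metabolites passing a VIP filter are
#' reduced to their mean case Z-scores, and those means are tested against 0
#' with a one-sample Wilcoxon signed-rank test (exact for small families).
#'
#' @param z Z-score tibble.
#' @param members metabolite IDs of the family.
#' @param model optional [fit_plsda()] fit used for the VIP filter; fitted
#'   internally when `NULL` and `min_vip > 0`.
#' @param min_vip VIP threshold members must exceed (default 0, no filter).
#' @return one-row tibble: `n_members`, `mean_z`, `se_z`, `p_value`.
#' @export
group_shift_test <- function(z, members, model = NULL, min_vip = 0) {
  ind <- require_both_classes(z$group)
  x <- met_matrix(z)
  unknown <- setdiff(members, colnames(x))
  if (length(unknown) > 0) {
    stop_input("unknown metabolite(s): %s", paste(unknown, collapse = ", "))
  }
  keep <- members
  if (min_vip > 0) {
    if (is.null(model)) model <- fit_plsda(z)
    vips <- vip_scores(model)
    keep <- members[vips$vip[match(members, vips$metabolite_id)] > min_vip]
  }
  if (length(keep) == 0) {
    stop_input("no members remain after the VIP > %.2f filter", min_vip)
  }
  mean_z <- colMeans(x[ind, keep, drop = FALSE])
  if (all(mean_z == 0)) {
    p <- 1
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(mean_z, mu = 0, alternative = "two.sided",
                         exact = length(mean_z) <= 20 &&
                           !anyDuplicated(abs(mean_z[mean_z != 0])))
    )
    p <- min(1, ht$p.value)
  }
  tibble::tibble(
    n_members = length(keep),
    mean_z = mean(mean_z),
    se_z = stats::sd(mean_z) / sqrt(length(mean_z)),
    p_value = p
  )
}

#' PCA scree of a Z-score matrix
#'
#' Eigen-decomposition of the sample covariance of the (column-centered)
#' Z-scores; variance fractions sum to 1.
#'
#' @param z Z-score tibble with at least 2 samples.
#' @return tibble: `component`, `variance`, `proportion`, `cumulative`.
#' @export
pca_scree <- function(z) {
  x <- met_matrix(z)
  if (nrow(x) < 2) stop_input("PCA needs at least 2 samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  tibble::tibble(
    component = seq_along(v),
    variance = v,
    proportion = v / sum(v),
    cumulative = cumsum(v) / sum(v)
  )
}
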