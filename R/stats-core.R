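#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent groups. The exact null distribution
#' is used whenever the combined sample size is at most 20 and there are no
#' ties; otherwise a tie-corrected normal approximation with continuity
#' correction is used. The reported statistic is the U statistic for
#' `group_a` (number of (a, b) pairs with a > b, ties counting one half).
#'
#' @param group_a,group_b numeric vectors of at least 2 finite values each.
#' @return a one-row tibble with columns `statistic` (U for `group_a`),
#'   `p_value`, and `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(group_a, group_b) {
  for (g in list(group_a, group_b)) {
    if (!is.numeric(g) || sum(is.finite(g)) < 2) {
      stop_input("each group needs at least 2 finite numeric values")
    }
  }
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; adjusted values are capped at 1
#' and are monotone non-decreasing in the rank of the raw p-value.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return a tibble with columns `raw` and `adjusted`, in input order.
#' @export
bh_fdr <- function(pvals) {
  check_probability(pvals)
  tibble::tibble(raw = pvals, adjusted = stats::p.adjust(pvals, method = "BH"))
}

#' Storey q-values
#'
#' Estimates the proportion of true nulls pi0 from the tail of the p-value
#' distribution, then scales the Benjamini-Hochberg step-up quantity by pi0.
#' pi0 is estimated as `#\{p > lambda\} / (m (1 - lambda))` over a grid of
#' lambda values, smoothed with a natural cubic spline (3 df) and evaluated
#' at the largest lambda; estimates above 1 fall back to 1.
#'
#' @param pvals numeric vector of at least 10 p-values in \[0, 1\].
#' @param lambda_grid grid of lambda values in \[0, 1) used for pi0
#'   estimation; must contain at least 4 distinct values.
#' @return a tibble with columns `raw` and `q`; the pi0 estimate is attached
#'   as attribute `"pi0"`.
#' @export
storey_q <- function(pvals, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  check_probability(pvals)
  if (length(pvals) < 10) {
    stop_input("storey_q needs at least 10 p-values to estimate pi0")
  }
  check_probability(lambda_grid, "lambda grid values")
  lambda_grid <- sort(unique(lambda_grid))
  if (length(lambda_grid) < 4 || any(lambda_grid >= 1)) {
    stop_input("lambda grid must contain >= 4 distinct values below 1")
  }
  m <- length(pvals)
  pi0_raw <- vapply(lambda_grid,
                    function(l) sum(pvals > l) / (m * (1 - l)),
                    numeric(1))
  fit <- stats::smooth.spline(lambda_grid, pi0_raw, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda_grid))$y
  pi0 <- if (!is.finite(pi0) || pi0 > 1) 1 else max(pi0, 1 / m)
  q <- pmin(1, pi0 * stats::p.adjust(pvals, method = "BH"))
  out <- tibble::tibble(raw = pvals, q = q)
  attr(out, "pi0") <- pi0
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass convention: the sum of
#' hypergeometric probabilities of all tables at least as extreme (i.e. with
#' probability not exceeding that of the observed table) at fixed margins.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (`a b / c d`).
#' @return a one-row tibble with `statistic` (conditional MLE odds ratio),
#'   `p_value`, and `method = "exact"`.
#' @examples
#' fisher_exact_2x2(2, 8, 8, 2)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop_input("cell counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop_input("at least one margin must be positive")
  ht <- stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))
  tibble::tibble(
    statistic = unname(ht$estimate),
    p_value = min(1, ht$p.value),
    method = "exact"
  )
}

#' Area under the ROC curve from scores
#'
#' The probability that a randomly chosen case scores higher than a randomly
#' chosen control, with ties counting one half — the normalized Mann-Whitney
#' U statistic.
#'
#' @param scores numeric score vector (higher = more case-like).
#' @param labels group labels (see [mann_whitney_u()]); both classes must be
#'   present.
#' @return a single number in \[0, 1\].
#' @export
auroc_from_scores <- function(scores, labels) {
  if (!is.numeric(scores) || anyNA(scores)) {
    stop_input("scores must be numeric and non-missing")
  }
  ind <- require_both_classes(labels)
  if (length(scores) != length(ind)) {
    stop_input("scores and labels must have equal length")
  }
  n1 <- sum(ind)
  n0 <- sum(!ind)
  r <- rank(scores)
  (sum(r[ind]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Contingency metrics for a diagnostic 2x2 table
#'
#' Sensitivity, specificity and accuracy with 95% Wilson score confidence
#' intervals for the two proportions.
#'
#' @param tp,fn,fp,tn non-negative counts; `tp + fn` and `fp + tn` must be
#'   positive.
#' @return a one-row tibble with the counts, point estimates, and CI bounds
#'   (`sensitivity_lo`/`_hi`, `specificity_lo`/`_hi`).
#' @examples
#' panel_contingency_metrics(19, 1, 2, 18)
#' @export
panel_contingency_metrics <- function(tp, fn, fp, tn) {
  counts <- c(tp, fn, fp, tn)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0)) {
    stop_input("counts must be non-negative")
  }
  if (tp + fn == 0 || fp + tn == 0) {
    stop_input("both the case (tp+fn) and control (fp+tn) margins must be positive")
  }
  sens_ci <- wilson_ci(tp, tp + fn)
  spec_ci <- wilson_ci(tn, tn + fp)
  tibble::tibble(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = tp / (tp + fn),
    sensitivity_lo = sens_ci[1], sensitivity_hi = sens_ci[2],
    specificity = tn / (tn + fp),
    specificity_lo = spec_ci[1], specificity_hi = spec_ci[2],
    accuracy = (tp + tn) / sum(counts)
  )
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}
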