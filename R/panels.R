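# Probability-forest scoring machinery shared by the panel operations.
# Scores are out-of-bag case probabilities, so apparent AUROC carries no
# resubstitution optimism.

fit_panel_forest <- function(x, labels, seed, num_trees) {
  df <- as.data.frame(x, check.names = FALSE)
  names(df) <- paste0("m", seq_len(ncol(df)))
  ranger::ranger(
    x = df, y = factor(labels, levels = GROUP_LEVELS),
    num.trees = num_trees, probability = TRUE,
    seed = seed, num.threads = 1,
    min.node.size = 5
  )
}

panel_oob_scores <- function(x, labels, seed, num_trees) {
  fit <- fit_panel_forest(x, labels, seed, num_trees)
  pred <- fit$predictions[, "case"]
  # Very small samples can leave an observation never out of bag.
  pred[is.na(pred)] <- 0.5
  pred
}

check_members <- function(z, members) {
  x <- met_matrix(z)
  unknown <- setdiff(members, colnames(x))
  if (length(unknown) > 0) {
    stop_input("unknown panel member(s): %s", paste(unknown, collapse = ", "))
  }
  x[, members, drop = FALSE]
}

# Youden's J operating point on OOB scores -> 2x2 counts.
youden_table <- function(scores, ind) {
  thr <- sort(unique(scores))
  best <- NULL
  best_j <- -Inf
  for (t in thr) {
    pred_case <- scores >= t
    sens <- sum(pred_case & ind) / sum(ind)
    spec <- sum(!pred_case & !ind) / sum(!ind)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best <- c(tp = sum(pred_case & ind), fn = sum(!pred_case & ind),
                fp = sum(pred_case & !ind), tn = sum(!pred_case & !ind))
    }
  }
  best
}

#' Evaluate a 1-6 metabolite diagnostic panel
#'
#' Fits a seeded probability forest on the panel's Z-score columns and
#' reports: out-of-bag AUROC with a bootstrap-percentile 95% CI
#' (`n_boot` resamples of the score/label pairs), a 2x2 contingency table at
#' the Youden's J operating point with Wilson CIs, the repeated double
#' cross-validation score ([rdcv_score()]), and, when `n_perm > 0`, an
#' empirical permutation p-value ([permutation_pvalue()]).
#'
#' @param z Z-score tibble.
#' @param members character vector of metabolite IDs (1-6 typical).
#' @param n_boot bootstrap resamples for the AUROC CI and rdCV splits
#'   (default 100).
#' @param n_perm label permutations for the empirical p (default 0 = skip).
#' @param seed integer seed; all resampling derives from it.
#' @param num_trees forest size (default 500).
#' @return an object of class `panel_eval`: one-row tibble with `members`
#'   (list column), `n_members`, `auroc`, `auroc_lo`, `auroc_hi`,
#'   contingency columns (see [panel_contingency_metrics()]), `rdcv`,
#'   `permutation_p` (`NA` when `n_perm = 0`), `seed`.
#' @export
evaluate_panel <- function(z, members, n_boot = 100, n_perm = 0,
                           seed = 1L, num_trees = 500) {
  ind <- require_both_classes(z$group)
  x <- check_members(z, members)
  scores <- panel_oob_scores(x, z$group, seed = derive_seed(seed, 1),
                             num_trees = num_trees)
  auroc <- auroc_from_scores(scores, z$group)

  boot <- withr::with_seed(derive_seed(seed, 2), {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(length(scores), replace = TRUE)
        if (any(ind[idx]) && !all(ind[idx])) break
      }
      auroc_from_scores(scores[idx], ind[idx])
    }, numeric(1))
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, type = 7)

  tab <- youden_table(scores, ind)
  cm <- panel_contingency_metrics(unname(tab["tp"]), unname(tab["fn"]),
                                  unname(tab["fp"]), unname(tab["tn"]))

  rdcv <- rdcv_score(z, members, n_boot = n_boot,
                     seed = derive_seed(seed, 3), num_trees = num_trees)
  perm_p <- NA_real_
  if (n_perm > 0) {
    perm_p <- permutation_pvalue(z, members, B = n_perm,
                                 seed = derive_seed(seed, 4),
                                 num_trees = num_trees)
  }
  n_members <- length(members)
  out <- dplyr::bind_cols(
    tibble::tibble(members = list(members), n_members = n_members,
                   auroc = auroc, auroc_lo = ci[1], auroc_hi = ci[2]),
    cm,
    tibble::tibble(rdcv = rdcv, permutation_p = perm_p,
                   seed = as.integer(seed))
  )
  class(out) <- c("panel_eval", class(out))
  out
}

#' Repeated double cross-validation score
#'
#' Mean held-out AUROC over `n_boot` stratified random splits with
#' `train_fraction` of each class in the training set and the remainder
#' held out; the forest is refit on every split. Deterministic given the
#' seed.
#'
#' @inheritParams evaluate_panel
#' @param train_fraction fraction of each class used for training (default
#'   2/3).
#' @return mean held-out AUROC (single number).
#' @export
rdcv_score <- function(z, members, n_boot = 100, train_fraction = 2 / 3,
                       seed = 1L, num_trees = 500) {
  ind <- require_both_classes(z$group)
  x <- check_members(z, members)
  case_idx <- which(ind)
  ctrl_idx <- which(!ind)
  n_case_tr <- floor(train_fraction * length(case_idx))
  n_ctrl_tr <- floor(train_fraction * length(ctrl_idx))
  if (n_case_tr < 1 || n_ctrl_tr < 1 ||
      n_case_tr >= length(case_idx) || n_ctrl_tr >= length(ctrl_idx)) {
    stop_input("too few samples for stratified %.0f%%/%.0f%% splits",
               100 * train_fraction, 100 * (1 - train_fraction))
  }
  aucs <- withr::with_seed(derive_seed(seed, 11), {
    vapply(seq_len(n_boot), function(b) {
      tr <- c(sample(case_idx, n_case_tr), sample(ctrl_idx, n_ctrl_tr))
      te <- setdiff(seq_along(ind), tr)
      fit <- fit_panel_forest(x[tr, , drop = FALSE], z$group[tr],
                              seed = derive_seed(seed, 100 + b),
                              num_trees = num_trees)
      df_te <- as.data.frame(x[te, , drop = FALSE], check.names = FALSE)
      names(df_te) <- paste0("m", seq_len(ncol(df_te)))
      p_case <- stats::predict(fit, data = df_te,
                               num.threads = 1)$predictions[, "case"]
      auroc_from_scores(p_case, ind[te])
    }, numeric(1))
  })
  mean(aucs)
}

#' Empirical permutation p-value for a panel
#'
#' Permutes the case/control labels `B` times, recomputes the statistic
#' (out-of-bag forest AUROC by default, or the rdCV score), and reports
#' `p = (1 + #\{permuted >= observed\}) / (B + 1)` — never 0.
#'
#' @inheritParams evaluate_panel
#' @param B number of permutations (>= 1).
#' @param statistic `"auroc"` (default) or `"rdcv"`.
#' @param rdcv_n_boot splits per rdCV evaluation when
#'   `statistic = "rdcv"` (default 25).
#' @return the empirical p-value.
#' @export
permutation_pvalue <- function(z, members, B = 1000, seed = 1L,
                               statistic = c("auroc", "rdcv"),
                               num_trees = 500, rdcv_n_boot = 25) {
  statistic <- match.arg(statistic)
  if (B < 1) stop_input("B must be at least 1")
  ind <- require_both_classes(z$group)
  x <- check_members(z, members)

  stat_fun <- function(labels, stat_seed) {
    if (statistic == "auroc") {
      scores <- panel_oob_scores(x, labels, seed = stat_seed,
                                 num_trees = num_trees)
      auroc_from_scores(scores, labels)
    } else {
      z_perm <- z
      z_perm$group <- labels
      rdcv_score(z_perm, members, n_boot = rdcv_n_boot,
                 seed = stat_seed, num_trees = num_trees)
    }
  }
  observed <- stat_fun(z$group, derive_seed(seed, 21))
  perm <- withr::with_seed(derive_seed(seed, 22), {
    vapply(seq_len(B), function(b) {
      stat_fun(sample(z$group), derive_seed(seed, 1000 + b))
    }, numeric(1))
  })
  (1 + sum(perm >= observed - 1e-12)) / (B + 1)
}

#' Grow nested diagnostic panels by greedy forward selection
#'
#' Starting from the best single candidate by rdCV score, greedily adds the
#' candidate that maximizes the rdCV score at each step, emitting a full
#' [evaluate_panel()] for every size 1..`max_size` — a report in the shape
#' of a diagnostic-performance table. Selection uses `n_boot_select` splits
#' per candidate; final evaluations use `n_boot` (and `n_perm`
#' permutations).
#'
#' @param screen a [screen_metabolites()] tibble supplying candidates.
#' @param z Z-score tibble.
#' @param max_size largest panel size (default 6).
#' @param n_candidates number of top-VIP candidates considered (default 12).
#' @param candidates optional explicit candidate IDs (overrides
#'   `screen`-based selection).
#' @param n_boot_select rdCV splits per candidate during selection.
#' @inheritParams evaluate_panel
#' @return tibble of stacked `panel_eval` rows, one per panel size.
#' @export
grow_panels <- function(screen, z, max_size = 6, n_candidates = 12,
                        candidates = NULL, n_boot_select = 25,
                        n_boot = 100, n_perm = 0, seed = 1L,
                        num_trees = 500) {
  require_both_classes(z$group)
  if (is.null(candidates)) {
    candidates <- utils::head(screen$metabolite_id, n_candidates)
  }
  if (length(candidates) < max_size) {
    stop_input("need at least max_size (%d) candidates, got %d",
               max_size, length(candidates))
  }
  chosen <- character(0)
  rows <- vector("list", max_size)
  for (size in seq_len(max_size)) {
    pool <- setdiff(candidates, chosen)
    sel_scores <- vapply(pool, function(cand) {
      rdcv_score(z, c(chosen, cand), n_boot = n_boot_select,
                 seed = derive_seed(seed, 30 + size), num_trees = num_trees)
    }, numeric(1))
    chosen <- c(chosen, pool[which.max(sel_scores)])
    rows[[size]] <- evaluate_panel(z, chosen, n_boot = n_boot,
                                   n_perm = n_perm,
                                   seed = derive_seed(seed, 60 + size),
                                   num_trees = num_trees)
  }
  dplyr::bind_rows(rows)
}

#' Per-group sample size for a future two-group study
#'
#' Normal-approximation sample size for a two-sided two-sample comparison
#' at standardized effect size `effect_size`:
#' `n = 2 (z_{1-alpha/2} + z_{power})^2 / d^2` per group, then increased by
#' `n_predictors` subjects per group as a degrees-of-freedom allowance for
#' selecting that many predictors in a multiple regression model. The
#' convention is reported in the output so downstream users know exactly
#' what was computed.
#'
#' @param effect_size standardized difference d (> 0); default 0.51.
#' @param alpha two-sided type I error (default 0.05).
#' @param power target power (default 0.8).
#' @param n_predictors predictors to be selected (default 6); set 0 for the
#'   plain two-group formula.
#' @return one-row tibble: `n_per_group`, `base_n`, `effect_size`, `alpha`,
#'   `power`, `n_predictors`, `convention`.
#' @examples
#' required_sample_size(effect_size = 0.8, n_predictors = 0) # 25 per group
#' @export
required_sample_size <- function(effect_size = 0.51, alpha = 0.05,
                                 power = 0.8, n_predictors = 6) {
  if (!is.numeric(effect_size) || effect_size <= 0) {
    stop_input("effect_size must be positive")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_input("alpha and power must lie in (0, 1)")
  }
  base_n <- 2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 /
    effect_size^2
  tibble::tibble(
    n_per_group = as.integer(ceiling(base_n) + n_predictors),
    base_n = base_n,
    effect_size = effect_size, alpha = alpha, power = power,
    n_predictors = as.integer(n_predictors),
    convention = "normal approximation, two-sample two-sided; + n_predictors per group df allowance"
  )
}
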