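# Shared fixtures, all generated in code.

# A tiny deterministic cohort: 6 samples x 4 metabolites, intensities chosen
# by hand so control stats are easy to verify.
tiny_cohort <- function() {
  tibble::tibble(
    sample_id = c("c1", "c2", "c3", "g1", "g2", "g3"),
    group = c("control", "control", "control", "case", "case", "case"),
    met_a = c(1, 2, 3, 5, 6, 7),
    met_b = c(10, 20, 30, 25, 15, 5),
    met_c = c(2, 2, 2, 2, 2, 2),        # constant
    met_d = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5)
  )
}

# Simulated cohort already log-transformed and Z-scored.
sim_zscores <- function(seed = 1, ...) {
  sim <- generate_cohort(cohort_config(seed = seed, ...))
  z <- zscore_against_controls(log_transform(sim$cohort))
  list(z = z, annotation = sim$annotation, truth = sim$truth)
}

# A small, fully separable two-metabolite cohort for classifier sanity
# checks (case values strictly above control values).
separable_cohort <- function(n = 10) {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(2 * n)),
    group = rep(c("case", "control"), each = n),
    m1 = c(seq(10, 11, length.out = n), seq(1, 2, length.out = n)),
    m2 = c(seq(20, 21, length.out = n), seq(5, 6, length.out = n))
  )
}

# Exhaustive two-sided Mann-Whitney p by label-permutation enumeration
# (independent oracle for small untied samples).
mw_exact_p_enum <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  mu <- n_a * length(b) / 2
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force AUROC: fraction of case/control pairs won (ties half).
auroc_brute <- function(scores, is_case) {
  ca <- scores[is_case]
  co <- scores[!is_case]
  (sum(outer(ca, co, ">")) + 0.5 * sum(outer(ca, co, "=="))) /
    (length(ca) * length(co))
}
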