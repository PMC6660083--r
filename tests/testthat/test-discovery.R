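test_that("PLS-DA separates a separable toy and keeps scores orthogonal", {
  z <- separable_cohort()
  fit <- fit_plsda(z, n_components = 2)
  s1 <- fit$scores[, 1]
  is_case <- z$group == "case"
  expect_true(min(s1[is_case]) > max(s1[!is_case]) ||
                max(s1[is_case]) < min(s1[!is_case]))
  expect_gt(sum(fit$ssy) / fit$total_y_ss, 0.95)
  if (fit$n_components > 1) {
    expect_lt(abs(sum(fit$scores[, 1] * fit$scores[, 2])), 1e-8)
  }
  expect_equal(colSums(fit$weights^2), rep(1, fit$n_components),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("component-1 weight is the dominant eigenvector of X'yy'X", {
  set.seed(31)
  z <- tibble::tibble(
    sample_id = paste0("s", 1:5),
    group = c("case", "case", "control", "control", "control"),
    !!!setNames(as.data.frame(matrix(rnorm(30), 5, 6)), paste0("m", 1:6))
  )
  fit <- fit_plsda(z, n_components = 1)
  xc <- scale(as.matrix(z[paste0("m", 1:6)]), center = TRUE, scale = FALSE)
  y <- as.numeric(z$group == "case")
  yc <- y - mean(y)
  mat <- crossprod(xc, yc) %*% crossprod(yc, xc) # X'y y'X
  ev <- eigen(mat, symmetric = TRUE)$vectors[, 1]
  w <- fit$weights[, 1]
  expect_equal(abs(sum(w * ev)), 1, tolerance = 1e-8) # equal up to sign
})

test_that("PLS-DA input contracts are enforced", {
  z <- separable_cohort()
  expect_error(fit_plsda(dplyr::mutate(z, group = "case")),
               class = "metscreen_input_error")
  expect_error(fit_plsda(z, n_components = 25),
               class = "metscreen_input_error")
})

test_that("VIP follows the Wold identity and symmetry", {
  # single metabolite -> VIP exactly 1
  z1 <- separable_cohort()[, c("sample_id", "group", "m1")]
  expect_equal(vip_scores(fit_plsda(z1, 1))$vip, 1)

  # two exchangeable, equally informative metabolites -> both VIP 1
  z2 <- separable_cohort()[, c("sample_id", "group", "m1", "m2")]
  z2$m2 <- z2$m1 + rep(c(0.001, -0.001), 10) # near-exchangeable
  v2 <- vip_scores(fit_plsda(z2, 1))$vip
  expect_equal(v2, c(1, 1), tolerance = 1e-3)

  # sum of squared VIPs = number of metabolites on random instances
  set.seed(47)
  for (i in 1:10) {
    n <- sample(8:14, 1)
    p <- sample(4:12, 1)
    z <- tibble::tibble(
      sample_id = paste0("s", 1:n),
      group = rep_len(c("case", "control"), n),
      !!!setNames(as.data.frame(matrix(rnorm(n * p), n, p)),
                  paste0("m", 1:p))
    )
    fit <- fit_plsda(z, n_components = 2)
    expect_equal(sum(vip_scores(fit)$vip^2), p, tolerance = 1e-8)
  }
})

test_that("the metabolite screen applies the joint VIP and U rule", {
  sim <- sim_zscores(seed = 8)
  scr <- screen_metabolites(sim$z)
  expect_equal(scr$significant, scr$vip > 1.5 & scr$p_value <= 0.05)
  expect_equal(scr$direction, ifelse(scr$mean_case_z >= 0, "up", "down"))
  # ranked by VIP descending
  expect_true(all(diff(scr$vip) <= 1e-12))
  expect_equal(scr$rank, seq_len(nrow(scr)))
  # planted up-shifted pathway over-represented among top 30
  top30 <- dplyr::left_join(utils::head(scr, 30), sim$truth$planted,
                            by = "metabolite_id")
  cer_frac_top <- mean(top30$pathway == "ceramide")
  expect_gt(cer_frac_top, 31 / 358) # fold enrichment > 1
})

test_that("diagnosis correlations equal closed-form point-biserial values", {
  z <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    group = c(rep("control", 3), rep("case", 3)),
    m_lin = c(1, 2, 3, 4, 5, 6),
    m_ind = c(0, 0, 0, 1, 1, 1),
    m_const = rep(2, 6)
  )
  res <- diagnosis_correlations(z)
  r_lin <- res$pearson_r[res$metabolite_id == "m_lin"]
  expect_equal(r_lin, cor(1:6, c(0, 0, 0, 1, 1, 1)), tolerance = 1e-12)
  expect_equal(r_lin, 0.8783101, tolerance = 1e-6)
  expect_equal(res$spearman_rho[res$metabolite_id == "m_lin"], r_lin,
               tolerance = 1e-12) # ranks equal values here
  expect_equal(res$pearson_r[res$metabolite_id == "m_ind"], 1)
  expect_equal(res$pearson_r[res$metabolite_id == "m_const"], 0)
  expect_true(res$constant[res$metabolite_id == "m_const"])
})

test_that("random-forest ranking is seeded and finds a strong metabolite", {
  set.seed(61)
  n <- 40
  z <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n),
    group = rep(c("case", "control"), each = n / 2),
    !!!setNames(as.data.frame(matrix(rnorm(n * 20), n, 20)),
                sprintf("noise_%02d", 1:20))
  )
  z$signal <- rnorm(n) + ifelse(z$group == "case", 2.5, 0)
  r1 <- rf_rank(z, seed = 5)
  r2 <- rf_rank(z, seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$metabolite_id[1], "signal")
})

test_that("group shift test matches signed-rank enumeration", {
  # all member case means zero -> p = 1
  z0 <- tibble::tibble(
    sample_id = paste0("s", 1:8),
    group = rep(c("case", "control"), each = 4),
    m1 = c(1, -1, 2, -2, 5, 1, 2, 0), # case mean 0
    m2 = c(3, -3, 0.5, -0.5, 1, 1, 4, 2)
  )
  expect_equal(group_shift_test(z0, c("m1", "m2"))$p_value, 1)

  # 6 members all shifted up -> exact two-sided p = 2 / 2^6
  set.seed(71)
  n <- 12
  mets <- sprintf("fam_%d", 1:6)
  vals <- matrix(rnorm(n * 6), n, 6)
  vals[1:6, ] <- vals[1:6, ] + matrix(rep(seq(2, 3, length.out = 6),
                                          each = 6), 6, 6)
  z6 <- dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", 1:n),
                   group = rep(c("case", "control"), each = 6)),
    setNames(as.data.frame(vals), mets)
  )
  res <- group_shift_test(z6, mets)
  expect_equal(res$p_value, 2 / 64, tolerance = 1e-12)
  expect_gt(res$mean_z, 0)
  expect_error(group_shift_test(z6, "absent"),
               class = "metscreen_input_error")
})

test_that("a coherently shifted family reaches significance at study scale", {
  # 18-member family planted at +0.9 among null background, 20 vs 20
  cat18 <- tibble::tibble(
    metabolite_id = c(sprintf("fam_%02d", 1:18), sprintf("bg_%02d", 1:30)),
    pathway = c(rep("family", 18), rep("background", 30))
  )
  eff <- tibble::tibble(pathway = "family", mean_z_shift = 0.9,
                        affected_fraction = 1)
  hits <- vapply(1:10, function(i) {
    sim <- generate_cohort(cohort_config(catalog = cat18, effects = eff,
                                         seed = 600 + i))
    z <- zscore_against_controls(log_transform(sim$cohort))
    group_shift_test(z, sprintf("fam_%02d", 1:18))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("PCA scree fractions are a valid spectrum", {
  sim <- sim_zscores(seed = 2, n_cases = 6, n_controls = 6)
  scree <- pca_scree(sim$z)
  expect_equal(sum(scree$proportion), 1, tolerance = 1e-12)
  expect_equal(scree$cumulative[nrow(scree)], 1, tolerance = 1e-12)
  expect_true(all(diff(scree$proportion) <= 1e-12))

  # rank-1 toy: first component carries everything
  z1 <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    group = c("case", "case", "control", "control"),
    a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(-1, -2, -3, -4)
  )
  expect_equal(pca_scree(z1)$proportion[1], 1, tolerance = 1e-12)

  # 3x3 toy against a direct eigen oracle
  z3 <- tibble::tibble(
    sample_id = paste0("s", 1:3),
    group = c("case", "control", "control"),
    a = c(1, 0, 2), b = c(0, 3, 1), c = c(2, 1, 0)
  )
  ev <- eigen(cov(as.matrix(z3[c("a", "b", "c")])))$values
  expect_equal(pca_scree(z3)$proportion,
               (ev / sum(ev))[seq_len(nrow(pca_scree(z3)))],
               tolerance = 1e-8)
})
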