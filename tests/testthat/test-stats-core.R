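test_that("Mann-Whitney U matches exact enumeration on small untied samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1) # 2 of the 20 label assignments are as extreme
  expect_equal(res$method, "exact")

  set.seed(42)
  for (i in 1:12) {
    n_a <- sample(2:4, 1)
    n_b <- sample(2:4, 1)
    vals <- sample(100, n_a + n_b) / 7 # untied
    a <- vals[seq_len(n_a)]
    b <- vals[-seq_len(n_a)]
    expect_equal(mann_whitney_u(a, b)$p_value, mw_exact_p_enum(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U handles identical groups, ties and bad input", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  with_ties <- mann_whitney_u(c(1, 1, 2, 3), c(1, 2, 2, 4))
  expect_equal(with_ties$method, "normal_approx")
  expect_true(with_ties$p_value > 0 && with_ties$p_value <= 1)
  big <- mann_whitney_u(rnorm(15), rnorm(15))
  expect_equal(big$method, "normal_approx") # combined n > 20
  expect_error(mann_whitney_u(numeric(0), c(1, 2)),
               class = "metscreen_input_error")
  expect_error(mann_whitney_u(c(1, NA), c(1, 2)),
               class = "metscreen_input_error")
})

test_that("BH adjustment is a capped, rank-monotone step-up", {
  expect_equal(bh_fdr(c(0.2, 0.2, 0.2))$adjusted, c(0.2, 0.2, 0.2))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$adjusted, rep(0.04, 4))
  set.seed(7)
  p <- runif(50)
  adj <- bh_fdr(p)$adjusted
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "metscreen_input_error")
})

test_that("Storey q-values scale BH by a sane pi0 estimate", {
  set.seed(11)
  p <- runif(1000)
  res <- storey_q(p)
  pi0 <- attr(res, "pi0")
  expect_gte(pi0, 0.85)
  expect_lte(pi0, 1)
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_true(all(diff(res$q[order(p)]) >= -1e-12))
  # q = pi0 * BH everywhere (capped), so pi0 = 1 reduces to BH exactly
  expect_equal(res$q, pmin(1, pi0 * bh_fdr(p)$adjusted))
  # strong signal mixture: pi0 well below 1
  p_mix <- c(runif(300, 0, 1e-4), runif(700))
  expect_lt(attr(storey_q(p_mix), "pi0"), 0.95)
  expect_error(storey_q(runif(5)), class = "metscreen_input_error")
  expect_error(storey_q(runif(20), lambda_grid = c(0.1, 0.2)),
               class = "metscreen_input_error")
})

test_that("Fisher exact p sums hypergeometric mass of extreme tables", {
  expect_equal(fisher_exact_2x2(2, 8, 8, 2)$p_value, 4252 / 184756,
               tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  expect_lt(fisher_exact_2x2(902, 63001, 589, 63314)$p_value, 1e-4)
  # symmetric under simultaneous row and column swap
  expect_equal(fisher_exact_2x2(3, 9, 7, 2)$p_value,
               fisher_exact_2x2(2, 7, 9, 3)$p_value, tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), class = "metscreen_input_error")
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), class = "metscreen_input_error")
})

test_that("AUROC equals the normalized Mann-Whitney U and brute force", {
  expect_equal(
    auroc_from_scores(c(1, 2, 3, 10, 11, 12),
                      c(rep("control", 3), rep("case", 3))), 1)
  set.seed(99)
  for (i in 1:50) {
    n1 <- sample(3:8, 1)
    n0 <- sample(3:8, 1)
    scores <- sample(10, n1 + n0, replace = TRUE) # ties likely
    is_case <- c(rep(TRUE, n1), rep(FALSE, n0))
    a <- auroc_from_scores(scores, is_case)
    expect_equal(a, auroc_brute(scores, is_case), tolerance = 1e-12)
    u <- mann_whitney_u(scores[is_case], scores[!is_case])$statistic
    expect_equal(a, u / (n1 * n0), tolerance = 1e-12)
  }
  # null expectation at larger n
  set.seed(5)
  expect_equal(auroc_from_scores(rnorm(2000), rep(c(TRUE, FALSE), 1000)),
               0.5, tolerance = 0.05)
  expect_error(auroc_from_scores(1:4, rep(TRUE, 4)),
               class = "metscreen_input_error")
})

test_that("AUROC agrees with an independent ROC implementation", {
  set.seed(123)
  scores <- rnorm(40)
  labels <- rep(c("case", "control"), 20)
  expect_equal(
    auroc_from_scores(scores, labels),
    as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores,
      levels = c("control", "case"), direction = "<", quiet = TRUE))),
    tolerance = 1e-12
  )
})

test_that("contingency metrics and Wilson intervals are correct", {
  m <- panel_contingency_metrics(19, 1, 2, 18)
  expect_equal(m$sensitivity, 0.95)
  expect_equal(m$specificity, 0.90)
  expect_equal(m$accuracy, 37 / 40)
  expect_true(m$sensitivity_lo <= m$sensitivity &&
                m$sensitivity <= m$sensitivity_hi)
  expect_true(m$specificity_lo <= m$specificity &&
                m$specificity <= m$specificity_hi)

  perfect <- panel_contingency_metrics(20, 0, 0, 20)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  # Wilson closed form at z = qnorm(0.975), x/n = 19/20
  z <- qnorm(0.975)
  p <- 0.95
  n <- 20
  ctr <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(m$sensitivity_lo, ctr - half, tolerance = 1e-12)
  expect_equal(m$sensitivity_hi, ctr + half, tolerance = 1e-12)

  expect_error(panel_contingency_metrics(0, 0, 2, 18),
               class = "metscreen_input_error")
  expect_error(panel_contingency_metrics(1, -1, 2, 18),
               class = "metscreen_input_error")
})
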