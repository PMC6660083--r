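test_that("pairwise edges enumerate every unordered pair once", {
  sim <- sim_zscores(seed = 41, n_cases = 6, n_controls = 6)
  ids <- setdiff(names(sim$z), c("sample_id", "group"))
  z20 <- sim$z[, c("sample_id", "group", ids[1:20])]
  edges <- pairwise_edges(z20, "case")
  expect_equal(nrow(edges), 20 * 19 / 2)
  expect_false(any(edges$metabolite_a == edges$metabolite_b))
  key <- paste(pmin(edges$metabolite_a, edges$metabolite_b),
               pmax(edges$metabolite_a, edges$metabolite_b))
  expect_false(anyDuplicated(key) > 0)

  z2 <- sim$z[, c("sample_id", "group", ids[1:2])]
  expect_equal(nrow(pairwise_edges(z2, "control")), 1)
})

test_that("edge statistics behave on duplicated and constant columns", {
  withr::with_seed(51, {
    z <- tibble::tibble(
      sample_id = paste0("s", 1:10),
      group = rep(c("case", "control"), each = 5),
      a = rnorm(10), c = rep(1, 10)
    )
    z$b <- z$a # duplicate
  })
  edges <- pairwise_edges(z, "case")
  ab <- edges[edges$metabolite_a == "a" & edges$metabolite_b == "b", ]
  expect_equal(ab$pearson_r, 1)
  expect_equal(ab$p_value, 0)
  const_pairs <- edges[edges$metabolite_a == "c" | edges$metabolite_b == "c", ]
  expect_true(all(const_pairs$constant))
  expect_true(all(const_pairs$pearson_r == 0))
  expect_true(all(const_pairs$p_value == 1))
  expect_error(pairwise_edges(z[c(1:3, 6:10), ], "case"),
               class = "metscreen_input_error")
})

test_that("significant-pair counting partitions by sign", {
  sim <- sim_zscores(seed = 42)
  edges <- pairwise_edges(sim$z, "control")
  cnt <- count_significant(edges)
  expect_equal(cnt$positive + cnt$negative, cnt$total)
  expect_equal(cnt$total, sum(edges$fdr < 0.05))
  none <- count_significant(dplyr::mutate(edges, fdr = 1))
  expect_equal(none$total, 0)
  # planted block structure: significant pairs are dominated by
  # within-pathway pairs
  ann <- sim$annotation
  sig <- edges[edges$fdr < 0.05, ]
  same_pw <- ann$pathway[match(sig$metabolite_a, ann$metabolite_id)] ==
    ann$pathway[match(sig$metabolite_b, ann$metabolite_id)]
  expect_gt(mean(same_pw), 0.5)
})

test_that("network comparison reproduces count arithmetic and degeneracies", {
  cmp <- compare_pair_counts(20, 10, 100)
  expect_equal(cmp$ratio, 2)
  expect_equal(cmp$fisher_p,
               fisher_exact_2x2(20, 80, 10, 90)$p_value, tolerance = 1e-12)

  sim <- sim_zscores(seed = 43, n_cases = 8, n_controls = 8)
  ids <- setdiff(names(sim$z), c("sample_id", "group"))[1:30]
  zsub <- sim$z[, c("sample_id", "group", ids)]
  e_case <- pairwise_edges(zsub, "case")
  self_cmp <- compare_networks(e_case, e_case)
  expect_equal(self_cmp$ratio, 1)
  expect_equal(self_cmp$fisher_p, 1)

  e_bad <- pairwise_edges(zsub[, 1:20], "control")
  expect_error(compare_networks(e_case, e_bad),
               class = "metscreen_input_error")
})

test_that("null data yield almost no significant pairs", {
  frac <- vapply(1:5, function(i) {
    withr::with_seed(700 + i, {
      z <- dplyr::bind_cols(
        tibble::tibble(sample_id = paste0("s", 1:20),
                       group = rep(c("case", "control"), each = 10)),
        setNames(as.data.frame(matrix(rnorm(20 * 50), 20, 50)),
                 paste0("m", 1:50))
      )
    })
    cnt <- count_significant(pairwise_edges(z, "control"))
    cnt$total / nrow(pairwise_edges(z, "control"))
  }, numeric(1))
  expect_lt(mean(frac), 0.005)
})

test_that("network export filters, writes valid files, and round-trips", {
  dir <- withr::local_tempdir()
  sim <- sim_zscores(seed = 44, n_cases = 8, n_controls = 8)
  ids <- setdiff(names(sim$z), c("sample_id", "group"))[1:40]
  zsub <- sim$z[, c("sample_id", "group", ids)]
  edges <- pairwise_edges(zsub, "case")
  jp <- file.path(dir, "net.json")
  gp <- file.path(dir, "net.graphml")

  kept <- export_network(edges, jp, gp, r_min = 0.6,
                         annotation = sim$annotation)
  expect_equal(nrow(kept), sum(edges$pearson_r >= 0.6))
  parsed <- jsonlite::fromJSON(jp)
  expect_equal(nrow(parsed$links), nrow(kept))
  expect_setequal(
    paste(parsed$links$source, parsed$links$target),
    paste(kept$metabolite_a, kept$metabolite_b))
  g <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(kept))

  # absolute mode includes strong negatives
  kept_abs <- export_network(edges, NULL, NULL, r_min = 0.6,
                             mode = "absolute")
  expect_equal(nrow(kept_abs), sum(abs(edges$pearson_r) >= 0.6))

  # threshold above 1 -> empty but valid files
  empty <- export_network(edges, jp, gp, r_min = 1.01)
  expect_equal(nrow(empty), 0)
  parsed_empty <- jsonlite::fromJSON(jp)
  expect_equal(length(parsed_empty$links), 0)
})

test_that("neighbor subnetworks rank partners and exclude the query", {
  sim <- sim_zscores(seed = 45, n_cases = 120, n_controls = 10)
  edges <- pairwise_edges(sim$z, "case")
  hub <- sim$annotation$metabolite_id[1] # first ceramide cluster member
  nb <- neighbor_subnetwork(edges, hub, top_k = 7,
                            annotation = sim$annotation)
  expect_equal(nrow(nb), 7)
  expect_false(hub %in% nb$partner)
  expect_true(all(diff(abs(nb$spearman_rho)) <= 1e-12))
  # strongest partners live in the hub's own correlation cluster
  cluster_mates <- sim$annotation$metabolite_id[2:8]
  expect_gt(mean(nb$partner %in% cluster_mates), 0.5)

  ids <- setdiff(names(sim$z), c("sample_id", "group"))[1:5]
  small <- pairwise_edges(sim$z[, c("sample_id", "group", ids)], "case")
  expect_equal(nrow(neighbor_subnetwork(small, ids[1], top_k = 99)), 4)
  expect_error(neighbor_subnetwork(small, "absent"),
               class = "metscreen_input_error")
})
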