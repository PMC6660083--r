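#' Pairwise metabolite correlation edges within one group
#'
#' Pearson and Spearman correlations for every unordered metabolite pair
#' over one group's Z-scores, with p-values from the t-approximation
#' (`t = r sqrt(n - 2) / sqrt(1 - r^2)`), Benjamini-Hochberg FDR and Storey
#' q-values computed over all pairs within the group (on the Spearman
#' p-values, which also drive downstream edge significance). Constant
#' metabolites yield correlation 0 with `constant = TRUE`.
#'
#' @param z Z-score tibble.
#' @param group `"case"` or `"control"`; that group must have >= 4 samples.
#' @return tibble with `m(m-1)/2` rows: `metabolite_a`, `metabolite_b`,
#'   `pearson_r`, `pearson_p`, `spearman_rho`, `p_value`, `fdr`, `q`,
#'   `constant`, `group`.
#' @export
pairwise_edges <- function(z, group = c("case", "control")) {
  group <- match.arg(group)
  x <- met_matrix(z)[z$group == group, , drop = FALSE]
  n <- nrow(x)
  if (n < 4) stop_input("group '%s' has %d samples; >= 4 required", group, n)
  m <- ncol(x)
  if (m < 2) stop_input("need at least 2 metabolites")

  const <- apply(x, 2, function(col) stats::sd(col) == 0)
  r_p <- suppressWarnings(stats::cor(x))
  r_s <- suppressWarnings(stats::cor(apply(x, 2, rank)))

  ut <- upper.tri(r_p)
  idx <- which(ut, arr.ind = TRUE)
  pearson_r <- r_p[ut]
  spearman_rho <- r_s[ut]
  const_pair <- const[idx[, 1]] | const[idx[, 2]]
  pearson_r[const_pair | !is.finite(pearson_r)] <- 0
  spearman_rho[const_pair | !is.finite(spearman_rho)] <- 0

  cor_p <- function(r) {
    r2 <- pmin(abs(r), 1 - 1e-15)
    t_stat <- r2 * sqrt(n - 2) / sqrt(1 - r2^2)
    p <- 2 * stats::pt(-t_stat, df = n - 2)
    p[abs(r) >= 1] <- 0
    p[const_pair] <- 1
    p
  }
  p_s <- cor_p(spearman_rho)
  p_p <- cor_p(pearson_r)
  # Storey's pi0 needs a p-value ensemble; with very few pairs fall back to
  # pi0 = 1 (q = BH).
  q <- if (length(p_s) >= 10) storey_q(p_s)$q
       else bh_fdr(p_s)$adjusted

  tibble::tibble(
    metabolite_a = colnames(x)[idx[, 1]],
    metabolite_b = colnames(x)[idx[, 2]],
    pearson_r = pearson_r,
    pearson_p = p_p,
    spearman_rho = spearman_rho,
    p_value = p_s,
    fdr = bh_fdr(p_s)$adjusted,
    q = q,
    constant = const_pair,
    group = group
  )
}

#' Count significant edges
#'
#' Edges with `fdr < fdr_threshold`, split by the sign of the Spearman
#' correlation.
#'
#' @param edges a [pairwise_edges()] tibble.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return one-row tibble: `total`, `positive`, `negative`.
#' @export
count_significant <- function(edges, fdr_threshold = 0.05) {
  sig <- edges$fdr < fdr_threshold
  tibble::tibble(
    total = sum(sig),
    positive = sum(sig & edges$spearman_rho > 0),
    negative = sum(sig & edges$spearman_rho < 0)
  )
}

#' Compare interactome coupling from significant-pair counts
#'
#' Given the number of significantly correlated pairs in each group out of
#' the same total, reports the case/control ratio and a two-sided Fisher
#' exact test on the 2x2 table `{significant, not} x {case, control}`.
#'
#' @param sig_case,sig_control significant pair counts.
#' @param n_pairs total unordered pairs per group.
#' @return one-row tibble: `n_pairs_total`, `significant_case`,
#'   `significant_control`, `ratio`, `fisher_p`.
#' @export
compare_pair_counts <- function(sig_case, sig_control, n_pairs) {
  if (sig_case > n_pairs || sig_control > n_pairs) {
    stop_input("significant counts cannot exceed the number of pairs")
  }
  ft <- fisher_exact_2x2(sig_case, n_pairs - sig_case,
                         sig_control, n_pairs - sig_control)
  ratio <- if (sig_control > 0) {
    sig_case / sig_control
  } else if (sig_case == 0) {
    1 # two empty edge sets are identical
  } else {
    Inf
  }
  tibble::tibble(
    n_pairs_total = n_pairs,
    significant_case = sig_case,
    significant_control = sig_control,
    ratio = ratio,
    fisher_p = ft$p_value
  )
}

#' Differential coupling between case and control networks
#'
#' Counts FDR-significant pairs in each group's edge table and compares
#' them with [compare_pair_counts()]; also reports positive/negative
#' splits.
#'
#' @param case_edges,control_edges [pairwise_edges()] tibbles over the same
#'   metabolite set.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return one-row tibble: totals, per-group significant counts with
#'   positive/negative splits, `ratio`, `fisher_p`.
#' @export
compare_networks <- function(case_edges, control_edges,
                             fdr_threshold = 0.05) {
  key <- function(e) paste(e$metabolite_a, e$metabolite_b)
  if (!identical(sort(key(case_edges)), sort(key(control_edges)))) {
    stop_input("edge tables cover different metabolite pair sets")
  }
  cc <- count_significant(case_edges, fdr_threshold)
  ct <- count_significant(control_edges, fdr_threshold)
  cmp <- compare_pair_counts(cc$total, ct$total, nrow(case_edges))
  dplyr::bind_cols(
    cmp,
    tibble::tibble(
      positive_case = cc$positive, negative_case = cc$negative,
      positive_control = ct$positive, negative_control = ct$negative
    )
  )
}

#' Export a correlation network for visualization
#'
#' Writes a force-layout JSON file (nodes with `id` and pathway `group`;
#' links with `source`, `target`, `weight`, `sign`) and a GraphML file.
#' Only edges passing the display threshold are exported: by default signed
#' Pearson `r >= r_min`; set `mode = "absolute"` for `|r| >= r_min`.
#' Isolated nodes are dropped.
#'
#' @param edges a [pairwise_edges()] tibble.
#' @param json_path,graphml_path output paths (either may be `NULL` to
#'   skip).
#' @param r_min display threshold on Pearson r (default 0.85).
#' @param mode `"signed"` (default) or `"absolute"`.
#' @param annotation optional annotation tibble for node pathway colors.
#' @return the filtered edge tibble, invisibly.
#' @export
export_network <- function(edges, json_path = NULL, graphml_path = NULL,
                           r_min = 0.85, mode = c("signed", "absolute"),
                           annotation = NULL) {
  mode <- match.arg(mode)
  keep <- if (mode == "signed") edges$pearson_r >= r_min
          else abs(edges$pearson_r) >= r_min
  sub <- edges[keep, , drop = FALSE]
  nodes <- unique(c(sub$metabolite_a, sub$metabolite_b))
  pathway <- rep("unassigned", length(nodes))
  if (!is.null(annotation)) {
    hit <- match(nodes, annotation$metabolite_id)
    pathway[!is.na(hit)] <- annotation$pathway[hit[!is.na(hit)]]
  }
  node_tbl <- tibble::tibble(id = nodes, group = pathway)
  link_tbl <- tibble::tibble(
    source = sub$metabolite_a,
    target = sub$metabolite_b,
    weight = sub$pearson_r,
    sign = ifelse(sub$pearson_r >= 0, "positive", "negative")
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(nodes = node_tbl, links = link_tbl),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      as.data.frame(link_tbl), directed = FALSE,
      vertices = as.data.frame(node_tbl)
    )
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(sub)
}

#' First-neighbor subnetwork of one metabolite
#'
#' Top correlation partners of a query metabolite, ranked by absolute
#' Spearman correlation.
#'
#' @param edges a [pairwise_edges()] tibble.
#' @param metabolite_id query metabolite.
#' @param top_k number of partners to return (default 25; capped at m - 1).
#' @param annotation optional annotation tibble for partner pathways.
#' @return tibble: `partner`, `spearman_rho`, `pearson_r`, `fdr`, `sign`,
#'   `pathway`.
#' @export
neighbor_subnetwork <- function(edges, metabolite_id, top_k = 25,
                                annotation = NULL) {
  hit <- edges$metabolite_a == metabolite_id |
    edges$metabolite_b == metabolite_id
  if (!any(hit)) stop_input("metabolite '%s' not present in edges", metabolite_id)
  sub <- edges[hit, , drop = FALSE]
  partner <- ifelse(sub$metabolite_a == metabolite_id,
                    sub$metabolite_b, sub$metabolite_a)
  out <- tibble::tibble(
    partner = partner,
    spearman_rho = sub$spearman_rho,
    pearson_r = sub$pearson_r,
    fdr = sub$fdr,
    sign = ifelse(sub$spearman_rho >= 0, "positive", "negative")
  ) %>%
    dplyr::arrange(dplyr::desc(abs(.data$spearman_rho)), .data$partner) %>%
    utils::head(top_k)
  if (!is.null(annotation)) {
    out <- dplyr::left_join(
      out, dplyr::rename(annotation, partner = "metabolite_id"),
      by = "partner"
    )
  }
  out
}
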