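#' Pipeline configuration
#'
#' Bundles thresholds, resampling sizes and the global seed for
#' [run_full_pipeline()]. Either supply a measured `cohort` (+ `annotation`)
#' or a simulator configuration.
#'
#' @param cohort optional cohort tibble of raw intensities.
#' @param annotation optional annotation tibble; required with `cohort`.
#' @param simulate a [cohort_config()] used when no cohort is given.
#' @param vip_threshold,p_threshold joint screening rule (defaults 1.5,
#'   0.05).
#' @param fdr_threshold network edge FDR cutoff (default 0.05).
#' @param z_cut abnormality threshold on |Z| (default 2).
#' @param top_k metabolites aggregated into the pathway table (default 30).
#' @param r_min network display threshold on Pearson r (default 0.85).
#' @param n_boot bootstrap/rdCV resamples (default 100).
#' @param n_perm panel permutations (default 1000).
#' @param max_panel_size largest diagnostic panel (default 6).
#' @param n_candidates panel candidates taken from the top of the screen
#'   (default 12).
#' @param num_trees forest size for panel models (default 500).
#' @param seed global seed; per-stage seeds are derived from it by fixed
#'   offsets.
#' @param out_dir optional directory; when set, all report tables, network
#'   exports and a JSON run manifest are written there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, annotation = NULL,
                            simulate = cohort_config(),
                            vip_threshold = 1.5, p_threshold = 0.05,
                            fdr_threshold = 0.05, z_cut = 2,
                            top_k = 30, r_min = 0.85,
                            n_boot = 100, n_perm = 1000,
                            max_panel_size = 6, n_candidates = 12,
                            num_trees = 500,
                            seed = 1L, out_dir = NULL) {
  thresholds <- c(vip_threshold = vip_threshold, p_threshold = p_threshold,
                  fdr_threshold = fdr_threshold, z_cut = z_cut,
                  top_k = top_k, r_min = r_min)
  if (any(thresholds <= 0)) stop_config("all thresholds must be positive")
  if (!is.null(cohort) && is.null(annotation)) {
    stop_config("a measured cohort requires an annotation table")
  }
  structure(
    list(cohort = cohort, annotation = annotation, simulate = simulate,
         vip_threshold = vip_threshold, p_threshold = p_threshold,
         fdr_threshold = fdr_threshold, z_cut = z_cut, top_k = top_k,
         r_min = r_min, n_boot = n_boot, n_perm = n_perm,
         max_panel_size = max_panel_size, n_candidates = n_candidates,
         num_trees = num_trees, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full case-control metabolomics pipeline
#'
#' Executes preprocessing (log transform, control-referenced Z-scores),
#' PLS-DA screening, the pathway impact table, nested diagnostic panels,
#' per-group correlation networks with the differential coupling
#' comparison, and the diagnostic-vs-individualized abnormality partition.
#' Deterministic given `config$seed`; the seed fans out to per-stage seeds
#' by fixed offsets so stages can be rerun in isolation.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `met_pipeline`: list with `cohort`,
#'   `annotation`, `truth` (simulated runs only), `z`, `model`, `screen`,
#'   `scree`, `impact`, `panels`, `edges_case`, `edges_control`,
#'   `network_comparison`, `partition`, `rf_ranking`, `manifest`.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  truth <- NULL
  if (is.null(config$cohort)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- derive_seed(seed, 1)
    sim <- generate_cohort(sim_cfg)
    cohort <- sim$cohort
    annotation <- sim$annotation
    truth <- sim$truth
  } else {
    cohort <- validate_cohort(config$cohort)
    annotation <- validate_annotation(config$annotation,
                                      metabolite_ids(cohort))
  }

  z <- cohort %>% log_transform() %>% zscore_against_controls()
  model <- fit_plsda(z, n_components = 2)
  screen <- screen_metabolites(z, model,
                               vip_threshold = config$vip_threshold,
                               p_threshold = config$p_threshold)
  scree <- pca_scree(z)
  impact <- build_impact_table(screen, annotation, k = config$top_k)
  rf_ranking <- rf_rank(z, seed = derive_seed(seed, 2))
  panels <- grow_panels(screen, z,
                        max_size = config$max_panel_size,
                        n_candidates = config$n_candidates,
                        n_boot = config$n_boot, n_perm = config$n_perm,
                        seed = derive_seed(seed, 3),
                        num_trees = config$num_trees)
  edges_case <- pairwise_edges(z, "case")
  edges_control <- pairwise_edges(z, "control")
  network_comparison <- compare_networks(edges_case, edges_control,
                                         fdr_threshold = config$fdr_threshold)
  partition <- partition_abnormalities(z, screen, z_cut = config$z_cut,
                                       vip_threshold = config$vip_threshold)

  manifest <- list(
    package_version = as.character(utils::packageVersion("metscreen")),
    seed = seed,
    thresholds = list(
      vip_threshold = config$vip_threshold,
      p_threshold = config$p_threshold,
      fdr_threshold = config$fdr_threshold,
      z_cut = config$z_cut, top_k = config$top_k, r_min = config$r_min
    ),
    resampling = list(n_boot = config$n_boot, n_perm = config$n_perm,
                      num_trees = config$num_trees),
    n_samples = nrow(cohort),
    n_metabolites = length(metabolite_ids(cohort)),
    simulated = is.null(config$cohort)
  )

  result <- structure(
    list(cohort = cohort, annotation = annotation, truth = truth, z = z,
         model = model, screen = screen, scree = scree, impact = impact,
         panels = panels, edges_case = edges_case,
         edges_control = edges_control,
         network_comparison = network_comparison,
         partition = partition, rf_ranking = rf_ranking,
         manifest = manifest),
    class = "met_pipeline"
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config)
  }
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  readr::write_csv(result$screen, path("metabolite_screen.csv"),
                   progress = FALSE)
  readr::write_csv(impact_table_display(result$impact),
                   path("pathway_impact.csv"), progress = FALSE)
  panels_flat <- result$panels %>%
    dplyr::mutate(members = purrr::map_chr(.data$members, paste,
                                           collapse = ";"))
  readr::write_csv(panels_flat, path("panel_performance.csv"),
                   progress = FALSE)
  readr::write_csv(result$edges_case, path("edges_case.csv"),
                   progress = FALSE)
  readr::write_csv(result$edges_control, path("edges_control.csv"),
                   progress = FALSE)
  readr::write_csv(result$network_comparison,
                   path("network_comparison.csv"), progress = FALSE)
  readr::write_csv(result$partition$per_subject,
                   path("abnormality_partition.csv"), progress = FALSE)
  readr::write_csv(result$scree, path("pca_scree.csv"), progress = FALSE)
  export_network(result$edges_case, json_path = path("network_case.json"),
                 graphml_path = path("network_case.graphml"),
                 r_min = config$r_min, annotation = result$annotation)
  export_network(result$edges_control,
                 json_path = path("network_control.json"),
                 graphml_path = path("network_control.graphml"),
                 r_min = config$r_min, annotation = result$annotation)
  jsonlite::write_json(result$manifest, path("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' @export
print.met_pipeline <- function(x, ...) {
  cat("Case-control metabolomics pipeline run\n")
  cat(sprintf("  %d samples x %d metabolites (seed %d%s)\n",
              x$manifest$n_samples, x$manifest$n_metabolites,
              x$manifest$seed,
              if (x$manifest$simulated) ", simulated" else ""))
  cat(sprintf("  significant metabolites: %d\n", sum(x$screen$significant)))
  cat(sprintf("  hit pathways: %d (top: %s)\n", nrow(x$impact),
              if (nrow(x$impact)) x$impact$pathway[1] else "none"))
  cat(sprintf("  best panel AUROC: %.2f (size %d)\n",
              max(x$panels$auroc), x$panels$n_members[which.max(x$panels$auroc)]))
  cat(sprintf("  network coupling ratio (case/control): %.2f\n",
              x$network_comparison$ratio))
  invisible(x)
}
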