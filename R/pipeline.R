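## End-to-end orchestration: simulate (or read) -> normalize -> smooth ->
## call clusters -> map features -> metagene profiles -> rank -> DE, with
## per-stage outputs and a machine-readable summary.

#' Pipeline configuration
#'
#' Aggregates the simulation configuration and every stage parameter at
#' its standard default: cluster rule P < 0.01 / min run 100 bp / max gap
#' 250 bp, smoothing bandwidth 150 bp, DE rule 1.5-fold / difference >
#' 100 / P < 0.05 / floor 600, ranking window 200 bp. `top_n` defaults to
#' a tenth of the simulated gene count so the ranking stays selective on
#' toy genomes.
#'
#' @param seed Master seed; also seeds the simulation config.
#' @param sim A [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param annotation_path,chrom_sizes_path Optional: read the annotation
#'   from files instead of simulating (both must be given together).
#' @param bandwidth_bp,p_threshold,min_run_bp,max_gap_bp Signal/cluster
#'   parameters.
#' @param fold_threshold,min_difference,alpha,floor,floor_fraction DE
#'   parameters.
#' @param window_bp,top_n Sliding-window ranking parameters.
#' @param n_strata Gene-length strata for metagene profiles.
#' @param out_dir Optional output directory for per-stage files.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sim = sim_config(seed = seed),
                            annotation_path = NULL, chrom_sizes_path = NULL,
                            bandwidth_bp = 150, p_threshold = 0.01,
                            min_run_bp = 100, max_gap_bp = 250,
                            fold_threshold = 1.5, min_difference = 100,
                            alpha = 0.05, floor = 600, floor_fraction = 0.5,
                            window_bp = 200, top_n = NULL,
                            n_strata = 3, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(inherits(sim, "sim_config"),
            bandwidth_bp >= 0, p_threshold > 0, p_threshold <= 1,
            min_run_bp >= 0, max_gap_bp >= 0,
            fold_threshold >= 1, min_difference >= 0,
            alpha > 0, alpha <= 1, window_bp > 0, n_strata >= 2)
  if (is.null(cfg$top_n)) cfg$top_n <- max(10, round(sim$n_orfs / 10))
  if (!is.null(annotation_path) && is.null(chrom_sizes_path))
    stop("chrom_sizes_path is required with annotation_path")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; keys under `sim:`
#' are passed to [sim_config()].
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  if (!is.null(sim_args) && is.null(sim_args$seed) && !is.null(y$seed))
    sim_args$seed <- y$seed
  y$sim <- do.call(sim_config, as.list(sim_args))
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages: genome (simulated or read) -> TREX2-like ChIP tracks ->
#' quantile normalization -> smoothing -> binding clusters -> feature
#' mapping, enriched genes and metagene profiles -> sliding-window
#' ranking -> Rrm3-like wild-type and mutant tracks -> cluster-length /
#' coverage comparison -> expression simulation -> DE calling and
#' structural statistics. Every output is a pure function of the
#' configuration; when `out_dir` is set, per-stage BED/bedGraph/TSV files
#' and a YAML summary are written.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with components `annotation`,
#'   `trex2` (smoothed track, clusters, stats, feature table, enriched
#'   genes, profiles, top genes), `rrm3` (per condition clusters/stats,
#'   length-comparison P, top-gene expression medians), `expression`
#'   (DE table, counts, recovery, structural comparisons) and `summary`
#'   (flat named list of the headline numbers).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$annotation_path)) {
    for (p in c(config$annotation_path, config$chrom_sizes_path))
      if (!file.exists(p)) stop("input file does not exist: ", p)
    annotation <- read_annotation(config$annotation_path,
                                  config$chrom_sizes_path)
  } else {
    annotation <- simulate_genome(config$sim)
  }
  genes <- orf_features(annotation)

  ## --- TREX2-like factor: gradient occupancy ---
  sim_t <- simulate_chip_tracks(annotation, config$sim, "TREX2")
  norm_t <- quantile_normalize(sim_t$track)
  sm_t <- smooth_track(norm_t, config$bandwidth_bp)
  cl_t <- call_clusters(sm_t, config$p_threshold, config$min_run_bp,
                        config$max_gap_bp)
  stats_t <- cluster_set_stats(cl_t, annotation)
  fmap <- map_clusters_to_features(cl_t, annotation)
  enr <- call_enriched_genes(cl_t, sm_t, annotation)
  prof_pct <- cluster_distribution_profile(cl_t, genes, annotation)
  prof_sig <- signal_mean_profile(sm_t, genes, annotation)
  top_t <- top_n_by_sliding_window(sm_t, genes, config$window_bp,
                                   config$top_n)
  enr_cor <- enrichment_expression_correlation(
    enr[enr$enriched, , drop = FALSE], annotation)

  ## --- Rrm3-like factor: wild type vs mutant ---
  rrm3 <- lapply(c(wild_type = "wild_type", mutant = "mutant"),
                 function(cond) {
    s <- simulate_chip_tracks(annotation, config$sim, "Rrm3", cond)
    sm <- smooth_track(quantile_normalize(s$track), config$bandwidth_bp)
    cl <- call_clusters(sm, config$p_threshold, config$min_run_bp,
                        config$max_gap_bp)
    top <- top_n_by_sliding_window(sm, genes, config$window_bp,
                                   config$top_n)
    expr <- genes$expression_level[match(top$gene_id, genes$id)]
    list(smoothed = sm, clusters = cl,
         stats = cluster_set_stats(cl, annotation),
         truth = s$truth,
         recovery = planted_span_recovery(cl, s$truth),
         top = top, top_median_expression = median(expr))
  })
  len_p <- compare_cluster_lengths(rrm3$mutant$clusters,
                                   rrm3$wild_type$clusters)

  ## --- expression: DE calling and structural statistics ---
  sim_e <- simulate_expression(annotation, config$sim)
  de <- call_de(sim_e$expression, "wild_type", "mutant",
                config$fold_threshold, config$min_difference, config$alpha,
                config$floor, config$floor_fraction)
  de_counts <- table(factor(de$call,
                            c("up", "down", "unchanged", "filtered_low")))
  rec <- de_recovery(de, sim_e$truth)
  down_ids <- de$gene_id[de$call == "down"]
  down_stats <- if (length(down_ids) >= 3)
    lapply(setNames(nm = c("length", "gc_fraction", "expression_level")),
           function(a) compare_to_genome(down_ids, annotation, a,
                                         expression_floor = config$floor))
    else NULL

  summary <- list(
    n_genes = nrow(genes),
    trex2_n_clusters = stats_t$n_clusters,
    trex2_mean_cluster_bp = stats_t$mean_length_bp,
    trex2_genome_coverage = stats_t$genome_coverage_fraction,
    trex2_frac_peaks_in_orfs = stats_t$fraction_peaks_in_ORFs,
    trex2_n_enriched_genes = sum(enr$enriched),
    trex2_enrichment_expression_r = enr_cor$r,
    rrm3_wt_mean_cluster_bp = rrm3$wild_type$stats$mean_length_bp,
    rrm3_mut_mean_cluster_bp = rrm3$mutant$stats$mean_length_bp,
    rrm3_wt_coverage = rrm3$wild_type$stats$genome_coverage_fraction,
    rrm3_mut_coverage = rrm3$mutant$stats$genome_coverage_fraction,
    rrm3_length_mw_p = len_p,
    rrm3_wt_top_median_expr = rrm3$wild_type$top_median_expression,
    rrm3_mut_top_median_expr = rrm3$mutant$top_median_expression,
    de_up = unname(de_counts[["up"]]), de_down = unname(de_counts[["down"]]),
    de_filtered_low = unname(de_counts[["filtered_low"]]),
    de_sensitivity = rec$sensitivity, de_fpr = rec$fpr)

  result <- structure(list(annotation = annotation, config = config,
    trex2 = list(smoothed = sm_t, clusters = cl_t, stats = stats_t,
                 feature_table = fmap, enriched = enr,
                 profile_cluster_percent = prof_pct,
                 profile_signal_mean = prof_sig, top = top_t,
                 truth = sim_t$truth,
                 enrichment_expression = enr_cor),
    rrm3 = c(rrm3, list(length_comparison_p = len_p)),
    expression = list(de = de, counts = de_counts, recovery = rec,
                      truth = sim_e$truth, down_vs_genome = down_stats),
    summary = summary), class = "pipeline_result")

  if (!is.null(config$out_dir)) .write_pipeline_outputs(result, config$out_dir)
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_features_bed(result$annotation$features, p("annotation.bed"))
  writeLines(paste(names(result$annotation$chromosomes),
                   result$annotation$chromosomes, sep = "\t"),
             p("chrom.sizes"))
  write_clusters_bed(result$trex2$clusters, p("trex2_clusters.bed"))
  sm <- result$trex2$smoothed
  write_bedgraph(sm$chrom, sm$pos, sm$signal, p("trex2_signal.bedGraph"))
  write_bedgraph(sm$chrom, sm$pos, -log10(sm$p_value),
                 p("trex2_neglog10p.bedGraph"))
  write.table(result$trex2$feature_table, p("feature_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$trex2$enriched, p("enriched_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- data.frame(bin = names(result$trex2$profile_cluster_percent),
                     cluster_percent =
                       as.numeric(result$trex2$profile_cluster_percent),
                     signal_mean =
                       as.numeric(result$trex2$profile_signal_mean))
  write.table(prof, p("metagene_profiles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$trex2$top, p("trex2_top_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (cond in c("wild_type", "mutant"))
    write_clusters_bed(result$rrm3[[cond]]$clusters,
                       p(paste0("rrm3_", cond, "_clusters.bed")))
  write.table(result$expression$de, p("de_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$expression$truth, p("de_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(lapply(result$summary, function(v)
    if (is.numeric(v)) signif(v, 10) else v), p("summary.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("pipeline_result (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  TREX2-like: %d clusters (mean %.0f bp, %.1f%% coverage), %d enriched genes\n",
              s$trex2_n_clusters, s$trex2_mean_cluster_bp,
              100 * s$trex2_genome_coverage, s$trex2_n_enriched_genes))
  cat(sprintf("  Rrm3-like: mean cluster %.0f bp (wt) vs %.0f bp (mutant), MW P = %.2g\n",
              s$rrm3_wt_mean_cluster_bp, s$rrm3_mut_mean_cluster_bp,
              s$rrm3_length_mw_p))
  cat(sprintf("  DE: %d up, %d down, %d floor-filtered; sensitivity %.2f, FPR %.3f\n",
              s$de_up, s$de_down, s$de_filtered_low,
              s$de_sensitivity, s$de_fpr))
  invisible(x)
}
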