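#' Pipeline configuration
#'
#' Settings for [run_pipeline()]. Defaults follow the package's standard
#' protocol: populations under 10 individuals are excluded from kinship
#' analysis, parentage is assigned under an error-rate grid of 1e-4,
#' 1e-3, 1e-2 and 5e-2 with 1e-4 as the primary rate, and LOD thresholds
#' are the 0.999 Monte-Carlo quantile.
#'
#' @param min_population_size Minimum sample size for the kinship stage.
#' @param error_rates Error-rate grid for the robustness check.
#' @param primary_error_rate Rate used for downstream migration analysis.
#' @param lod_quantile Quantile of the simulated unrelated-pair LOD
#'   distribution used as assignment threshold.
#' @param n_sim_threshold Unrelated pairs simulated per threshold.
#' @param min_shared_loci Minimum loci typed in both pair members.
#' @param n_perm Mantel permutations for the isolation-by-distance test.
#' @param rarefaction_step Step of the rarefaction g grid.
#' @param run_robustness Run the error-rate grid (default `TRUE`); turn
#'   off to save time when only the primary rate matters.
#' @param seed Master seed; per-stage seeds are derived from it by a
#'   fixed counter scheme so every stage is reproducible in isolation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_population_size = 10,
                            error_rates = c(1e-4, 1e-3, 1e-2, 5e-2),
                            primary_error_rate = 1e-4,
                            lod_quantile = 0.999,
                            n_sim_threshold = 10000,
                            min_shared_loci = 10,
                            n_perm = 9999,
                            rarefaction_step = 2,
                            run_robustness = TRUE,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(config, slice, stage) {
  # counter-based fan-out; stays well under 2^31
  (config$seed * 1009L + slice * 101L + stage) %% .Machine$integer.max
}

#' Run the full temporal analysis pipeline
#'
#' Per time slice: diversity table -> per-time rarefaction curves ->
#' Nei distance, PCoA and isolation-by-distance -> size filter ->
#' LOD threshold calibration -> parentage assignment (primary error rate,
#' plus the robustness grid) -> migration counts and rates -> directed
#' network, betweenness, fast-greedy clustering -> source/sink labels and
#' key nodes -> migration distance summary. Cross-slice: source/sink
#' persistence and the cluster-count table. Slices are analysed in
#' isolation; only the final summaries combine them. Deterministic under
#' the config seed.
#'
#' @param x A [msat_data] with `time_code` metadata.
#' @param config A [pipeline_config].
#' @param out_dir Optional directory; when given, every artifact is also
#'   written as CSV (stable ordering, byte-reproducible under the seed).
#' @return A list of class `report_bundle` with elements `tabulation`,
#'   `diversity`, `diversity_means`, `rarefaction`, `slices` (per-slice
#'   lists), `persistence`, `cluster_counts`, `pooled_distance_summary`,
#'   `config`.
#' @export
run_pipeline <- function(x, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(x, "msat_data"), inherits(config, "pipeline_config"))
  tab <- tabulate_by_time(x)
  div <- diversity_table(x)
  div$time_code <- x$populations$time_code[
    match(div$population, x$populations$population)]
  div_means <- group_means(div, by = "time_code")
  rare <- rarefaction_curves(x, step = config$rarefaction_step)

  slices <- list()
  for (tc in sort(unique(x$populations$time_code))) {
    sl <- time_slice(x, tc)
    res <- list(time_code = tc)

    gen_d <- nei_distance_matrix(sl)
    res$nei <- gen_d
    finite <- all(is.finite(unclass(gen_d)))
    res$pcoa <- if (finite)
      pcoa_ordination(gen_d, n_axes = min(nrow(sl$populations) - 1, 3))
    geo_d <- geographic_distance_matrix(sl)
    res$ibd <- ibd_test(gen_d, geo_d, n_perm = config$n_perm,
                        seed = stage_seed(config, tc, 1L))

    ksl <- filter_min_size(sl, config$min_population_size)
    res$kinship_populations <- ksl$populations$population
    thr_seed <- stage_seed(config, tc, 2L)
    res$pairs <- assign_parentage(
      ksl, error = config$primary_error_rate,
      min_shared_loci = config$min_shared_loci,
      quantile = config$lod_quantile, n_sim = config$n_sim_threshold,
      seed = thr_seed)
    if (config$run_robustness) {
      res$robustness <- error_rate_robustness(
        ksl, rates = config$error_rates, seed = thr_seed,
        min_shared_loci = config$min_shared_loci,
        quantile = config$lod_quantile, n_sim = config$n_sim_threshold)
    }
    res$counts <- migration_counts(res$pairs, ksl)
    res$rates <- migration_rates(res$counts)
    res$network <- build_network(res$counts, ksl)
    res$betweenness <- if (igraph::ecount(res$network) > 0)
      edge_betweenness_undirected(res$network)
    res$clustering <- cluster_migration(res$network)
    res$roles <- classify_source_sink(res$network)
    res$key_nodes <- key_nodes(res$network, res$clustering)
    res$distance_summary <- migration_distance_summary(res$network)
    slices[[paste0("time", tc)]] <- res
  }

  persistence <- source_sink_persistence(
    lapply(slices, function(s) s$roles))
  cc <- tibble::tibble(
    time_code = vapply(slices, function(s) s$time_code, numeric(1)),
    n_clusters = vapply(slices, function(s) s$clustering$n_clusters,
                        numeric(1)),
    Q = vapply(slices, function(s) s$clustering$Q, numeric(1)),
    n_isolated = vapply(slices, function(s)
      sum(network_degrees(s$network)$degree == 0), numeric(1)))
  pooled_edges <- dplyr::bind_rows(lapply(slices, function(s)
    s$distance_summary$edges))

  bundle <- structure(list(
    tabulation = tab, diversity = div, diversity_means = div_means,
    rarefaction = rare, slices = slices, persistence = persistence,
    cluster_counts = cc,
    pooled_distance_summary = distance_summary_from_edges(pooled_edges),
    config = config), class = "report_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

distance_summary_from_edges <- function(edges, conf = 0.95) {
  d <- edges$distance_km
  n <- length(d)
  ci <- c(NA_real_, NA_real_)
  if (n >= 2) {
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) *
      stats::sd(d) / sqrt(n)
    ci <- mean(d) + c(-half, half)
  }
  structure(list(edges = edges, summary = tibble::tibble(
    n_edges = n,
    mean_km = if (n) mean(d) else NA_real_,
    median_km = if (n) stats::median(d) else NA_real_,
    q1_km = if (n) unname(stats::quantile(d, 0.25)) else NA_real_,
    q3_km = if (n) unname(stats::quantile(d, 0.75)) else NA_real_,
    max_km = if (n) max(d) else NA_real_,
    ci_low_km = ci[1], ci_high_km = ci[2], ci_defined = n >= 2)),
    class = "migration_distance_summary")
}

#' Per-slice cluster counts
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @return A tibble `time_code`, `n_clusters`, `Q`, `n_isolated`.
#' @export
cluster_count_table <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  bundle$cluster_counts
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", length(x$slices), " time slice(s)\n", sep = "")
  print(x$cluster_counts)
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(obj, name) {
    readr::write_csv(obj, file.path(out_dir, paste0(name, ".csv")),
                     progress = FALSE)
  }
  wr(bundle$tabulation, "tabulation_by_time")
  wr(bundle$diversity, "diversity")
  wr(bundle$diversity_means, "diversity_means")
  wr(bundle$rarefaction, "rarefaction_curves")
  wr(bundle$persistence, "source_sink_persistence")
  wr(bundle$cluster_counts, "cluster_counts")
  wr(bundle$pooled_distance_summary$summary, "pooled_distance_summary")
  for (nm in names(bundle$slices)) {
    s <- bundle$slices[[nm]]
    wr(mat_to_tbl(s$nei), paste0(nm, "_nei_distance"))
    wr(s$pairs, paste0(nm, "_parentage_pairs"))
    wr(mat_to_tbl(s$counts), paste0(nm, "_migration_counts"))
    wr(s$rates, paste0(nm, "_migration_rates"))
    wr(s$roles, paste0(nm, "_source_sink"))
    wr(s$clustering$membership, paste0(nm, "_clusters"))
    wr(s$distance_summary$edges, paste0(nm, "_migration_edges"))
    wr(s$distance_summary$summary, paste0(nm, "_distance_summary"))
    wr(tibble::tibble(
      r = s$ibd$r, p = s$ibd$p, n_pairs = s$ibd$n_pairs,
      n_perm = s$ibd$n_perm, seed = s$ibd$seed), paste0(nm, "_ibd"))
  }
  invisible(out_dir)
}

mat_to_tbl <- function(m) {
  m <- unclass(m)
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(label = rownames(m)), out)
}
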