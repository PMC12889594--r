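#' @useDynLib plaqueomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# write a stage's JSON summary next to its TSV outputs
.write_summary <- function(out_dir, stage, summary) {
  summary$stage <- stage
  summary$package_version <- as.character(utils::packageVersion("plaqueomics"))
  jsonlite::write_json(summary,
                       file.path(out_dir, paste0(stage, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the simulate stage
#'
#' Generates a synthetic cohort, writes the matrix, metadata and planted
#' truth, and a JSON summary.
#'
#' @param out_dir Output directory.
#' @param config A [cohort_config()].
#' @return Invisibly, the cohort.
#' @export
run_stage_simulate <- function(out_dir, config = cohort_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  write_cohort(cohort, out_dir, config)
  .write_summary(out_dir, "simulate", list(
    seed = config$seed,
    n_proteins = nrow(cohort$matrix$values),
    n_samples = ncol(cohort$matrix$values),
    n_planted_daps = length(cohort$truth$dap_ids),
    frac_missing = mean(is.na(cohort$matrix$values))))
  invisible(cohort)
}

#' Run the QC stage
#'
#' Contaminant filter, minimum-detection filter, median normalization
#' and tracer extraction; writes the cleaned matrix and a QC summary.
#'
#' @param m An [IntensityMatrix] (or path handling via
#'   [read_intensity_matrix()] upstream).
#' @param out_dir Output directory.
#' @param contaminants Contaminant patterns.
#' @param min_samples Detection filter threshold (default 3).
#' @param tracer_id Optional tracer protein for QC reporting.
#' @return Invisibly, the cleaned [IntensityMatrix].
#' @export
run_stage_qc <- function(m, out_dir, contaminants = default_contaminants(),
                         min_samples = 3L, tracer_id = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m1 <- filter_contaminants(m, contaminants)
  n_con <- attr(m1, "n_removed")
  m2 <- filter_min_detection(m1, min_samples)
  n_det <- attr(m2, "n_removed")
  m3 <- median_normalize(m2)
  write_intensity_matrix(m3, file.path(out_dir, "matrix_qc.tsv"),
                         file.path(out_dir, "metadata_qc.tsv"))
  tracer_tab <- NULL
  if (!is.null(tracer_id) && tracer_id %in% rownames(m3$values)) {
    tracer_tab <- extract_tracer(m3, tracer_id)
    .write_tsv(tracer_tab, file.path(out_dir, "tracer.tsv"))
  }
  .write_summary(out_dir, "qc", list(
    n_contaminants_removed = n_con,
    n_low_detection_removed = n_det,
    n_proteins_retained = nrow(m3$values),
    n_samples = ncol(m3$values)))
  invisible(m3)
}

#' Run the differential abundance stage
#'
#' @param m Cleaned [IntensityMatrix].
#' @param out_dir Output directory.
#' @param fdr_threshold,alpha_g,min_pairs See [dap_analysis()].
#' @return Invisibly, the DAP record data frame.
#' @export
run_stage_dap <- function(m, out_dir, fdr_threshold = 0.05, alpha_g = 0.05,
                          min_pairs = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- dap_analysis_all(m, fdr_threshold = fdr_threshold,
                          alpha_g = alpha_g, min_pairs = min_pairs)
  .write_tsv(rec, file.path(out_dir, "dap_table.tsv"))
  .write_summary(out_dir, "dap", list(
    fdr_threshold = fdr_threshold, alpha_g = alpha_g,
    n_tested = sum(rec$tested), n_daps = sum(rec$is_dap),
    strata = as.list(table(rec$stratum[rec$is_dap]))))
  invisible(rec)
}

#' Run the temporal classification stage
#'
#' @param m Cleaned [IntensityMatrix] of one model across ages.
#' @param dap_ids DAP ids to classify.
#' @param out_dir Output directory.
#' @param tau,tol See [classify_trajectories()].
#' @return Invisibly, the trajectory table.
#' @export
run_stage_temporal <- function(m, dap_ids, out_dir, tau = 0.5, tol = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- classify_trajectories(m, dap_ids, tau = tau, tol = tol)
  .write_tsv(tab, file.path(out_dir, "temporal_clusters.tsv"))
  .write_summary(out_dir, "temporal", list(
    tau = tau, tol = tol, n_input = nrow(tab),
    n_excluded = sum(tab$excluded),
    clusters = as.list(table(tab$cluster[!tab$excluded]))))
  invisible(tab)
}

#' Run the co-expression network stage
#'
#' Correlation screen, PFN construction, module detection, hubs,
#' DAP-enrichment and module-trait correlation, written as TSVs.
#'
#' @param m Cleaned [IntensityMatrix].
#' @param out_dir Output directory.
#' @param z_stats Named `|log2FC-z|` vector for module enrichment
#'   (optional).
#' @param n_perm_edges,n_null_modules,n_perm_enrich Permutation counts.
#' @param seed Seed for all stochastic steps.
#' @return Invisibly, a list with `edges`, `pfn`, `detection`, `hubs`,
#'   `enrichment`, `trait`.
#' @export
run_stage_network <- function(m, out_dir, z_stats = NULL,
                              n_perm_edges = 100L, n_null_modules = 1000L,
                              n_perm_enrich = 10000L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  edges <- significant_correlations(m, n_perm = n_perm_edges, seed = seed)
  sig <- edges[edges$significant, , drop = FALSE]
  if (!nrow(sig)) stop("no significant correlations; network stage aborted")
  pfn <- build_pfn(sig)
  et <- igraph::graph_attr(pfn, "edge_table")
  .write_tsv(et, file.path(out_dir, "edges.tsv"))
  detection <- detect_modules(pfn, n_null = n_null_modules, seed = seed)
  hubs <- lapply(detection$modules$module_id[detection$modules$reported],
                 function(id) {
                   h <- find_hubs(pfn, detection$members[[id]], seed = seed)
                   h$module_id <- id
                   h
                 })
  hubs <- do.call(rbind, hubs)
  enr <- if (!is.null(z_stats))
    modules_enrichment(detection, z_stats, n_perm = n_perm_enrich, seed = seed)
  else NULL
  trait <- module_trait_correlation(detection, m)
  mod_tab <- detection$modules
  mod_tab$members <- vapply(detection$members[mod_tab$module_id],
                            paste, character(1), collapse = ";")
  .write_tsv(mod_tab, file.path(out_dir, "modules.tsv"))
  if (!is.null(hubs)) .write_tsv(hubs, file.path(out_dir, "hubs.tsv"))
  if (!is.null(enr)) .write_tsv(enr, file.path(out_dir, "module_enrichment.tsv"))
  .write_tsv(trait, file.path(out_dir, "module_trait.tsv"))
  .write_summary(out_dir, "network", list(
    seed = seed, n_edges_tested = nrow(edges), n_edges_significant = nrow(sig),
    n_edges_pfn = igraph::ecount(pfn), n_nodes_pfn = igraph::vcount(pfn),
    n_modules_reported = sum(detection$modules$reported),
    n_trait_associated = sum(trait$trait_associated)))
  invisible(list(edges = edges, pfn = pfn, detection = detection,
                 hubs = hubs, enrichment = enr, trait = trait))
}

#' Run the consensus ranking stage
#'
#' @param rankings List of study rankings (see [aggregate_rankings()]).
#' @param out_dir Output directory.
#' @param min_datasets Minimum-presence filter (default 3).
#' @return Invisibly, the aggregation result.
#' @export
run_stage_rank <- function(rankings, out_dir, min_datasets = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  agg <- aggregate_rankings(rankings, min_datasets = min_datasets)
  .write_tsv(agg$consensus, file.path(out_dir, "consensus.tsv"))
  .write_summary(out_dir, "rank", list(
    n_studies = length(rankings), min_datasets = min_datasets,
    n_ranked = nrow(agg$consensus), n_unrankable = nrow(agg$unrankable)))
  invisible(agg)
}

#' Run the overrepresentation stage
#'
#' @param daps Query protein set.
#' @param collection Gene sets from [read_gmt()].
#' @param out_dir Output directory.
#' @param fdr,min_fold See [fisher_ora()].
#' @return Invisibly, the enrichment table.
#' @export
run_stage_enrich <- function(daps, collection, out_dir, fdr = 0.01,
                             min_fold = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- fisher_ora(daps, collection, fdr = fdr, min_fold = min_fold)
  .write_tsv(tab, file.path(out_dir, "ora.tsv"))
  .write_summary(out_dir, "enrich", list(
    fdr = fdr, min_fold = min_fold, n_sets = nrow(tab),
    n_reported = sum(tab$reported)))
  invisible(tab)
}

#' Run the full synthetic pipeline end to end
#'
#' Simulate, QC, differential abundance, temporal classification and the
#' co-expression network stage on one synthetic cohort, writing every
#' stage's outputs under `out_dir` and a concatenated report.
#'
#' @param out_dir Output directory.
#' @param config A [cohort_config()].
#' @param n_perm_edges,n_null_modules,n_perm_enrich Permutation counts
#'   for the network stage.
#' @return Invisibly, a list of all stage results.
#' @export
run_pipeline <- function(out_dir, config = cohort_config(),
                         n_perm_edges = 100L, n_null_modules = 1000L,
                         n_perm_enrich = 1000L) {
  cohort <- run_stage_simulate(out_dir, config)
  qc <- run_stage_qc(cohort$matrix, out_dir, tracer_id = config$tracer_id)
  rec <- run_stage_dap(qc, out_dir)
  dap_ids <- unique(rec$protein_id[rec$is_dap])
  temporal <- if (length(dap_ids) >= 2)
    run_stage_temporal(qc, dap_ids, out_dir) else NULL
  # network on block + DAP proteins is the scientifically interesting part,
  # but the stage takes the full matrix; restrict to complete-enough rows
  z14 <- rec[rec$stratum == paste0(config$model, ":", max(config$ages)) &
               rec$tested, ]
  z_stats <- stats::setNames(abs(z14$z), z14$protein_id)
  net <- tryCatch(
    run_stage_network(qc, out_dir, z_stats = z_stats,
                      n_perm_edges = n_perm_edges,
                      n_null_modules = n_null_modules,
                      n_perm_enrich = n_perm_enrich, seed = config$seed),
    error = function(e) { warning("network stage: ", conditionMessage(e)); NULL })
  summaries <- Sys.glob(file.path(out_dir, "*_summary.json"))
  report <- lapply(summaries, jsonlite::read_json)
  names(report) <- sub("_summary\\.json$", "", basename(summaries))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, qc = qc, daps = rec, temporal = temporal,
                 network = net))
}
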