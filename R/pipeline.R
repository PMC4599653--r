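#' Run the full disease-similarity analysis
#'
#' Orchestrates the pipeline over a list of per-disease expression
#' datasets: per-gene differential coexpression (or the log-fold-change
#' baseline in DE mode), pathway-level aggregation, partial Spearman
#' similarity, membership-permutation null, empirical p and BH q values,
#' network construction, and — when annotations are supplied — the
#' downstream network statistics. All artifacts are written to
#' `out_dir` together with a provenance JSON; re-running with the same
#' inputs and seed reproduces the outputs bit-identically.
#'
#' @param datasets Named list of `ExpressionDataset` objects (one per
#'   disease; see [merge_by_disease_tissue()]).
#' @param pathways A `PathwayCollection`.
#' @param out_dir Output directory, created if absent.
#' @param mode `"dce"` (differential coexpression, default) or `"de"`
#'   (log fold change baseline).
#' @param q Neighbor percentile threshold for [neighbor_sets()].
#' @param reps Permutation depth for the similarity null.
#' @param seed Master seed.
#' @param p_threshold Edge-inclusion threshold.
#' @param covariate_mode Passed to [similarity_matrix()].
#' @param min_genes Passed to [pathway_dc_matrix()].
#' @param gene_assoc,drug_assoc Optional `AssociationTable`s for the
#'   sharing analysis.
#' @param annotation Optional `CategoryAnnotation` for the WD table.
#' @param tissue_map Optional named disease -> tissue vector for the
#'   tissue permutation analysis.
#' @param k_groups Optional group count for hierarchical clustering.
#' @param bins Degree-histogram bins.
#' @param force Passed to [null_distribution()].
#' @return Invisibly, a list with all in-memory results (`profiles`,
#'   `dc_matrix`, `similarity`, `pair_stats`, `network`, `analyses`,
#'   `manifest`).
#' @export
run_pipeline <- function(datasets, pathways, out_dir,
                         mode = c("dce", "de"), q = 0.75, reps = 500L,
                         seed = 1L, p_threshold = 0.05,
                         covariate_mode = "loo-mean", min_genes = 1L,
                         gene_assoc = NULL, drug_assoc = NULL,
                         annotation = NULL, tissue_map = NULL,
                         k_groups = NULL,
                         bins = list(c(1, 10), c(11, 20), c(21, 30), c(31, 40)),
                         force = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.list(datasets), length(datasets) >= 3L)
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, `[[`, character(1), "disease_id")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  emit <- function(obj, file, writer = NULL) {
    path <- file.path(out_dir, file)
    if (is.null(writer)) {
      utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else writer(obj, path)
    manifest <<- c(manifest, file)
    path
  }
  t0 <- proc.time()[["elapsed"]]
  stage_times <- c()
  tick <- function(stage) {
    now <- proc.time()[["elapsed"]]
    stage_times <<- c(stage_times, stats::setNames(now - t0, stage))
    t0 <<- now
  }

  profiles <- lapply(datasets, function(d) {
    if (mode == "dce") dc_profile(d, q = q) else log_fold_change(d)
  })
  prof_df <- do.call(rbind, lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    if (inherits(p, "DCProfile"))
      data.frame(disease = id, gene = p$gene, value = p$dC)
    else data.frame(disease = id, gene = names(p), value = unname(p))
  }))
  emit(prof_df, "gene_profiles.tsv")
  tick("profiles")

  dc_matrix <- pathway_dc_matrix(profiles, pathways, min_genes = min_genes)
  emit(data.frame(pathway = rownames(dc_matrix), dc_matrix,
                  check.names = FALSE), "pathway_values.tsv")
  tick("pathway_aggregation")

  sim <- similarity_matrix(dc_matrix, covariate_mode = covariate_mode)
  null <- null_distribution(profiles, pathways, reps = reps, seed = seed,
                            covariate_mode = covariate_mode,
                            min_genes = min_genes, force = force)
  pair_stats <- empirical_pvalues(sim, null)
  pair_stats$q <- bh_fdr(pair_stats$p)
  emit(pair_stats, "pair_statistics.tsv")
  tick("similarity_and_null")

  network <- build_network(pair_stats, p_threshold = p_threshold,
                           nodes = names(datasets))
  emit(network, "edges.tsv", write_edge_list)
  tick("network")

  analyses <- list()
  if (!is.null(annotation) && nrow(network$edges))
    analyses$category_wd <- emit_try(category_wd_table(network, annotation),
                                     emit, "category_wd.tsv")
  if (!is.null(tissue_map) && nrow(network$edges))
    analyses$tissue_wd <- emit_try(
      tissue_wd_permutation(network, tissue_map, reps = max(100L, reps),
                            seed = seed),
      emit, "tissue_wd.tsv")
  if (!is.null(k_groups)) {
    cl <- hierarchical_cluster(sim, pair_stats, k = k_groups,
                               p_threshold = p_threshold)
    analyses$clusters <- cl
    emit(data.frame(disease = names(cl), group = unname(cl)), "clusters.tsv")
  }
  if (nrow(network$edges))
    analyses$degree <- emit_try(degree_distribution(network, bins),
                                emit, "degree_histogram.tsv")
  for (kind in c("gene", "drug")) {
    assoc <- if (kind == "gene") gene_assoc else drug_assoc
    if (is.null(assoc) || !nrow(network$edges)) next
    tab <- sharing_contingency(network, assoc)
    fish <- ddl_vs_nonddl_fisher(tab)
    analyses[[paste0(kind, "_sharing")]] <- fish
    emit(data.frame(link = rownames(tab), tab, fisher_p = fish$p,
                    check.names = FALSE),
         paste0(kind, "_sharing.tsv"))
  }
  tick("network_analysis")

  provenance <- list(
    package_version = as.character(utils::packageVersion("dcnet")),
    mode = mode, q = q, reps = reps, seed = seed,
    p_threshold = p_threshold, covariate_mode = covariate_mode,
    min_genes = min_genes,
    n_diseases = length(datasets), n_pathways = length(pathways$sets),
    fdr_at_threshold = attr(network, "fdr"),
    stage_seconds = as.list(stage_times),
    manifest = manifest)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(profiles = profiles, dc_matrix = dc_matrix,
                 similarity = sim, null = null, pair_stats = pair_stats,
                 network = network, analyses = analyses,
                 manifest = c(manifest, "provenance.json")))
}

# run an analysis stage, emit its table, and degrade to NULL (with a
# warning) when the inputs cannot support the statistic
emit_try <- function(expr, emit, file) {
  res <- tryCatch(expr, error = function(e) {
    warning("analysis stage for ", file, " skipped: ", conditionMessage(e))
    NULL
  })
  if (!is.null(res)) emit(res, file)
  res
}
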