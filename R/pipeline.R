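#' Pipeline run configuration
#'
#' Validates and bundles everything one end-to-end run needs: either paths
#' to real inputs (CT table + target map + GMT) or a simulation block, the
#' analysis thresholds, the GSEA parameters, the root seed and the output
#' directory. Exactly one of `ct_path` / `simulate` must be given.
#'
#' @param ct_path path to a CT export readable by [read_ct_table()].
#' @param ct_format dialect of `ct_path` (`"wide"` or `"long"`).
#' @param sample_meta sample metadata for [read_ct_table()] (data.frame or
#'   path), if not inline.
#' @param target_map_path path to a miRNA-target TSV ([read_target_map()]).
#' @param gmt_path path to a GMT gene-set collection ([read_gmt()]).
#' @param simulate a [sim_config()]; when given, inputs are simulated and
#'   `target_map_path`/`gmt_path` may be omitted (annotations are simulated
#'   too via [simulate_targets_and_sets()]).
#' @param spike_in spike-in assay label (default `"cel-miR-39-3p"`).
#' @param ceiling limit-of-detection ceiling in cycles (default 40).
#' @param min_detected detection filter threshold (default 2).
#' @param q_de DE significance threshold on the BH q-value (default 0.2).
#' @param consistency_min patients required for a consistency call
#'   (default 3).
#' @param selection miRNA selection feeding the ranked list
#'   (`"all_retained"` or `"nominal_p"`).
#' @param n_perm,weight,min_size,max_size GSEA parameters
#'   (see [prerank_gsea()]). `min_size` defaults to 15.
#' @param p_network miRNA inclusion threshold for the network
#'   (default 0.05).
#' @param q_pathway pathway inclusion threshold (default 0.2).
#' @param seed root seed; all stage seeds are derived from it.
#' @param out_dir output directory (created if missing).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(ct_path = NULL, ct_format = "wide",
                       sample_meta = NULL,
                       target_map_path = NULL, gmt_path = NULL,
                       simulate = NULL,
                       spike_in = "cel-miR-39-3p", ceiling = 40,
                       min_detected = 2, q_de = 0.2, consistency_min = 3,
                       selection = "all_retained",
                       n_perm = 1000, weight = 1, min_size = 15,
                       max_size = 500,
                       p_network = 0.05, q_pathway = 0.2,
                       seed = 1, out_dir = tempfile("evmirna_run_")) {
  if (is.null(ct_path) == is.null(simulate))
    stop("exactly one of `ct_path` or `simulate` must be given")
  if (!is.null(simulate) && !inherits(simulate, "sim_config"))
    stop("`simulate` must be a sim_config()")
  if (is.null(simulate) &&
      (is.null(target_map_path) || is.null(gmt_path)))
    stop("real-data runs need `target_map_path` and `gmt_path`")
  for (thr in c(q_de = q_de, p_network = p_network, q_pathway = q_pathway))
    if (thr <= 0 || thr > 1) stop("thresholds must lie in (0, 1]")
  structure(list(
    ct_path = ct_path, ct_format = ct_format, sample_meta = sample_meta,
    target_map_path = target_map_path, gmt_path = gmt_path,
    simulate = simulate, spike_in = spike_in, ceiling = ceiling,
    min_detected = min_detected, q_de = q_de,
    consistency_min = consistency_min, selection = selection,
    n_perm = n_perm, weight = weight, min_size = min_size,
    max_size = max_size, p_network = p_network, q_pathway = q_pathway,
    seed = as.integer(seed), out_dir = out_dir), class = "run_config")
}

# per-stage seeds derived from the root so stages are individually
# reproducible; kept below 2^31
.stage_seed <- function(seed, stage) {
  (as.integer(seed) + 1000003L * match(stage, c("sim_ct", "sim_annot",
                                                "gsea"))) %% 2147483647L
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Chains read/simulate -> detection filter -> spike-in normalization ->
#' paired DE (+ PCA scores) -> target ranking -> preranked GSEA ->
#' tripartite network, writing every stage artifact into
#' `config$out_dir` together with a JSON manifest (file list with MD5
#' checksums, stage cardinalities mirroring the filtering cascade, seed and
#' package version). Identical config + seed produce byte-identical files.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- .stage("simulate", simulate_ct(config$simulate,
                                          seed = .stage_seed(config$seed,
                                                             "sim_ct")))
    ct <- sim$ct
    truth <- sim$truth
    annot <- .stage("simulate_annotations", simulate_targets_and_sets(
      truth, seed = .stage_seed(config$seed, "sim_annot")))
    targets <- annot$targets
    collection <- annot$collection
  } else {
    ct <- .stage("read_ct", read_ct_table(
      config$ct_path, config$ct_format, spike_in = config$spike_in,
      ceiling = config$ceiling, sample_meta = config$sample_meta))
    targets <- .stage("read_targets", read_target_map(config$target_map_path))
    collection <- .stage("read_gmt", read_gmt(config$gmt_path))
  }

  filt <- .stage("filter", filter_by_detection(ct, config$min_detected))
  expr <- .stage("normalize", normalize_spike_in(filt$ct))
  de <- .stage("diffexpr", run_differential_expression(
    expr, q_threshold = config$q_de,
    consistency_min = config$consistency_min))
  pca <- .stage("pca", pca_scores(expr, n_components = min(
    2L, nrow(expr$samples) - 1L, nrow(expr$expr))))
  ranked <- .stage("rank", build_ranked_list(de, targets, config$selection))
  enrich <- .stage("gsea", prerank_gsea(
    ranked, collection, n_perm = config$n_perm, weight = config$weight,
    min_size = config$min_size, max_size = config$max_size,
    seed = .stage_seed(config$seed, "gsea")))
  net <- .stage("network", build_network(
    de, targets, enrich, mirna_p = config$p_network,
    pathway_q = config$q_pathway))

  # stage artifacts
  write_filter_report(filt$report, out("filter_report.tsv"))
  write_filter_report(filt$report, out("filter_report.json"))
  write_expression(expr, out("expression.tsv"))
  de_out <- de
  utils::write.table(de_out, out("de_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(
    data.frame(sample_id = pca$sample_ids, pca$scores,
               check.names = FALSE),
    out("pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  write_rnk(ranked, out("ranked_genes.rnk"))
  utils::write.table(ranked, out("ranked_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  write_enrichment(enrich, out("enrichment.tsv"))
  export_network(net, out("network.graphml"), "graphml")
  export_network(net, out("network_edges.tsv"), "edge_tsv")
  utils::write.table(degree_summary(net), out("network_degrees.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")

  files <- c("filter_report.tsv", "filter_report.json", "expression.tsv",
             "de_table.tsv", "pca_scores.tsv", "ranked_genes.rnk",
             "ranked_genes.tsv", "enrichment.tsv", "network.graphml",
             "network_edges.tsv", "network_edges.tsv.nodes.tsv",
             "network_degrees.tsv")
  sums <- unname(tools::md5sum(vapply(files, out, character(1))))
  manifest <- list(
    package = "evmirna",
    version = as.character(utils::packageVersion("evmirna")),
    seed = config$seed,
    simulated = !is.null(config$simulate),
    stages = list(
      cascade = list(n_assays_total = filt$report$n_assays_total,
                     n_detected_any = filt$report$n_detected_any,
                     n_retained = filt$report$n_retained),
      n_patients = length(unique(expr$samples$patient_id)),
      n_tested = sum(!de$degenerate),
      n_significant_q = sum(de$significant),
      n_ranked_genes = nrow(ranked),
      n_gene_sets = nrow(enrich),
      n_significant_pathways = nrow(significant_pathways(
        enrich, config$q_pathway)),
      network = list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges))),
    files = stats::setNames(as.list(sums), files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, de = de, enrich = enrich, net = net,
                 ranked = ranked, expr = expr, report = filt$report,
                 truth = truth, out_dir = config$out_dir))
}
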