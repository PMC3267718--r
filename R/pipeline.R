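# End-to-end orchestration: simulate (or load) -> DABG detection cascade ->
# RMA at exon and gene level -> splicing index -> differential tables ->
# compound selection -> Venn/overlap summaries -> clustering + PCA ->
# optional over-representation analysis, with a manifest echoing every
# parameter, the stage-count ladder and output file hashes.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated object. Unknown
#' keys are rejected. `sim` may be a [sim_config()] or a list of its
#' arguments; pass input paths instead (`probes`, `background`, `annotation`,
#' `design` TSV/CSV files) to run on real data.
#'
#' @param sim a [sim_config()] or argument list for one (synthetic mode).
#' @param inputs named list of file paths (`probes`, `background`,
#'   `annotation`, `design`) for real-data mode; ignored when `sim` given.
#' @param dabg_alpha DABG significance cut-off for step-1 detection.
#' @param step1_min_fraction,step1_comparator step-1 within-group fraction
#'   and comparator (default `>=` 0.5).
#' @param step2_min_fraction,step2_comparator step-2 detected-member fraction
#'   and comparator (default strict `>` 0.5).
#' @param gc_bins GC bins for DABG.
#' @param variant t-test variant (`"pooled"`, `"welch"`, `"moderated"`).
#' @param criteria a [selection_criteria()].
#' @param gene_sets optional `gene_set_collection` (or GMT path) for ORA.
#' @param seed integer seed forwarded to the simulator when `sim` is a plain
#'   list without one.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, inputs = NULL,
                            dabg_alpha = 0.05,
                            step1_min_fraction = 0.5, step1_comparator = ">=",
                            step2_min_fraction = 0.5, step2_comparator = ">",
                            gc_bins = 4L, variant = "pooled",
                            criteria = selection_criteria(),
                            gene_sets = NULL, seed = NULL) {
  if (is.null(sim) && is.null(inputs)) {
    stop_schema("pipeline_config: provide either sim or inputs")
  }
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    if (!is.list(sim)) stop_schema("sim must be a sim_config or argument list")
    if (is.null(sim$seed)) sim$seed <- seed
    sim <- do.call(sim_config, sim)
  }
  if (!is.null(inputs)) {
    unknown <- setdiff(names(inputs), c("probes", "background", "annotation",
                                        "design", "background_gc"))
    if (length(unknown)) stop_schema("unknown input keys: ",
                                     paste(unknown, collapse = ", "))
  }
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  stopifnot(inherits(criteria, "selection_criteria"))
  structure(list(sim = sim, inputs = inputs, dabg_alpha = dabg_alpha,
                 step1_min_fraction = step1_min_fraction,
                 step1_comparator = step1_comparator,
                 step2_min_fraction = step2_min_fraction,
                 step2_comparator = step2_comparator,
                 gc_bins = as.integer(gc_bins), variant = variant,
                 criteria = criteria, gene_sets = gene_sets, seed = seed),
            class = "pipeline_config")
}

#' Read pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments (`criteria` given as a mapping of [selection_criteria()]
#'   arguments).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop_schema("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$criteria)) y$criteria <- do.call(selection_criteria, y$criteria)
  do.call(pipeline_config, y)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- simulate_exon_array(config$sim)
    return(list(probes = sim$probes, background = sim$background,
                annotation = sim$annotation, design = sim$design,
                truth = sim$truth))
  }
  inp <- config$inputs
  background <- read_matrix(inp$background, level = "probe", scale = "linear")
  if (!is.null(inp$background_gc)) {
    gc <- utils::read.table(inp$background_gc, header = TRUE, sep = "\t")
    attr(background, "gc_fraction") <- gc$gc_fraction[match(rownames(background),
                                                            gc$probe_id)]
  }
  list(probes = read_matrix(inp$probes, level = "probe", scale = "linear"),
       background = background,
       annotation = read_annotation(inp$annotation, level_filter = "core"),
       design = read_design(inp$design),
       truth = NULL)
}

#' Run the full pipeline
#'
#' Executes detection, preprocessing, differential testing, selection, set
#' comparison, clustering/PCA and (optionally) over-representation analysis.
#' With an output directory, writes every table as TSV plus a JSON manifest
#' (parameters, stage-count ladder, md5 of each table); reruns with the same
#' configuration write byte-identical numeric tables.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param out_dir optional output directory (created if missing).
#' @return object of class `exonsplice_run` with the detection state,
#'   matrices, differential tables, selections, set summaries, structure
#'   results, optional enrichment tables, truth evaluation (synthetic mode)
#'   and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  data <- load_pipeline_inputs(config)
  ann <- data$annotation
  design <- data$design
  groups <- unique(design$group)
  comparisons <- lapply(groups[-1L], function(g) c(groups[1L], g))
  cmp_names <- vapply(comparisons, paste, character(1), collapse = "_vs_")

  es_log("DABG on ", nrow(data$probes), " probes x ", ncol(data$probes), " samples")
  dabg <- compute_dabg(data$probes, data$background, ann, gc_bins = config$gc_bins)
  exon_det <- detect_exon_probesets(dabg, design, alpha = config$dabg_alpha,
                                    min_fraction = config$step1_min_fraction,
                                    comparator = config$step1_comparator)
  cluster_det <- detect_transcript_clusters(exon_det, ann,
                                            min_fraction = config$step2_min_fraction,
                                            comparator = config$step2_comparator)
  exon_mat <- rma_summarize(data$probes, ann, "exon_probeset")
  gene_mat <- rma_summarize(data$probes, ann, "transcript_cluster")
  rec <- reconcile_detectable(exon_det, cluster_det, gene_mat, ann)

  detection <- list(dabg_p = dabg, exon_detected = exon_det,
                    cluster_detected = cluster_det,
                    detectable_exon_ids = rec$detectable_exon_ids,
                    detectable_cluster_ids = rec$detectable_cluster_ids,
                    counts = rec$counts)

  gene_use <- gene_mat[rownames(gene_mat) %in% rec$detectable_cluster_ids, ,
                       drop = FALSE]
  exon_use <- exon_mat[rownames(exon_mat) %in% rec$detectable_exon_ids, ,
                       drop = FALSE]
  si <- splicing_index(exon_use, gene_mat, ann)

  gene_table <- build_differential_table(gene_use, design, comparisons,
                                         level = "gene", variant = config$variant)
  exon_table <- build_differential_table(si, design, comparisons,
                                         level = "exon", variant = config$variant)

  selections <- list()
  for (nm in cmp_names) {
    selections[[nm]] <- list(
      gene = select_features(gene_table, config$criteria, nm),
      exon = select_features(exon_table, config$criteria, nm),
      gene_clustering = select_for_clustering(gene_table, config$criteria, nm),
      exon_clustering = select_for_clustering(exon_table, config$criteria, nm))
  }

  # set comparisons at gene granularity (exon selections collapsed to clusters)
  spliced_clusters <- lapply(selections, function(s)
    collapse_to_clusters(s$exon, ann))
  setops <- list()
  if (length(cmp_names) >= 2L) {
    setops$de_venn <- venn2(selections[[1L]]$gene, selections[[2L]]$gene,
                            labels = cmp_names[1:2])
    setops$spliced_venn <- venn2(spliced_clusters[[1L]], spliced_clusters[[2L]],
                                 labels = cmp_names[1:2])
  }
  setops$overlap <- lapply(cmp_names, function(nm)
    overlap_summary(spliced_clusters[[nm]], selections[[nm]]$gene))
  names(setops$overlap) <- cmp_names

  structure_res <- run_structure_stage(gene_use, si, selections, cmp_names)

  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    sel_union <- unique(unlist(lapply(selections, `[[`, "gene")))
    if (length(sel_union)) {
      enrichment <- hypergeometric_ora(sel_union, rownames(gene_use),
                                       config$gene_sets)
    }
  }

  evaluation <- if (!is.null(data$truth)) {
    evaluate_against_truth(data$truth, selections, gene_table, cmp_names)
  }

  run <- structure(list(config = config, design = design, annotation = ann,
                        detection = detection, gene_matrix = gene_mat,
                        exon_matrix = exon_mat, splicing_index = si,
                        gene_table = gene_table, exon_table = exon_table,
                        selections = selections, setops = setops,
                        structure = structure_res, enrichment = enrichment,
                        evaluation = evaluation, manifest = NULL),
                   class = "exonsplice_run")
  if (!is.null(out_dir)) run <- write_run(run, out_dir)
  run
}

run_structure_stage <- function(gene_use, si, selections, cmp_names) {
  out <- list()
  # gene-level display set: union across comparisons of the 2-fold gate
  gene_ids <- unique(unlist(lapply(selections, `[[`, "gene_clustering")))
  if (length(gene_ids) >= 2L) {
    m <- median_center(gene_use[gene_ids, , drop = FALSE])
    ok <- apply(m, 1L, stats::var) > 0 # constant rows carry no ordering signal
    m <- m[ok, , drop = FALSE]
    if (nrow(m) >= 2L) {
      out$gene_sample_tree <- average_linkage(
        centered_correlation_distance(m, axis = "columns"))
      out$gene_feature_tree <- average_linkage(
        centered_correlation_distance(m, axis = "rows"))
      out$gene_heatmap <- m
    }
  }
  exon_ids <- unique(unlist(lapply(selections, `[[`, "exon_clustering")))
  if (length(exon_ids) >= 2L) {
    m <- median_center(si[exon_ids, , drop = FALSE])
    ok <- apply(m, 1L, stats::var) > 0
    m <- m[ok, , drop = FALSE]
    if (nrow(m) >= 2L) {
      out$si_sample_tree <- average_linkage(
        centered_correlation_distance(m, axis = "columns"))
      out$si_heatmap <- m
    }
  }
  out$pca <- pca(gene_use, n_components = min(3L, ncol(gene_use) - 1L))
  out
}

evaluate_against_truth <- function(truth, selections, gene_table, cmp_names) {
  out <- list()
  for (nm in cmp_names) {
    if (!paste0("log2_fold_", nm) %in% names(truth$clusters)) next
    de_true <- truth$clusters$cluster_id[truth$clusters$de_spiked]
    sp_true <- truth$probesets$probeset_id[truth$probesets$splice_spiked]
    sel <- selections[[nm]]
    out[[nm]] <- list(
      de_sensitivity = if (length(de_true))
        length(intersect(sel$gene, de_true)) / length(de_true) else NA_real_,
      de_precision = if (length(sel$gene))
        length(intersect(sel$gene, de_true)) / length(sel$gene) else NA_real_,
      splice_sensitivity = if (length(sp_true))
        length(intersect(sel$exon, sp_true)) / length(sp_true) else NA_real_,
      splice_precision = if (length(sel$exon))
        length(intersect(sel$exon, sp_true)) / length(sel$exon) else NA_real_,
      spiked_clusters_gene_selected = length(intersect(
        sel$gene,
        unique(truth$probesets$transcript_cluster_id[truth$probesets$splice_spiked]))))
  }
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wm <- function(mat, name) {
    p <- file.path(out_dir, name)
    write_matrix(mat, p)
    files[[name]] <<- p
  }
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    files[[name]] <<- p
  }
  wm(run$gene_matrix, "gene_level.tsv")
  wm(run$exon_matrix, "exon_level.tsv")
  wm(run$splicing_index, "splicing_index.tsv")
  wm(run$detection$dabg_p, "dabg_p.tsv")
  wt(data.frame(probeset_id = names(run$detection$exon_detected),
                detected = run$detection$exon_detected,
                detectable = names(run$detection$exon_detected) %in%
                  run$detection$detectable_exon_ids),
     "detection_exon.tsv")
  wt(run$gene_table, "differential_gene.tsv")
  wt(run$exon_table, "differential_exon.tsv")
  for (nm in names(run$selections)) {
    wt(data.frame(feature_id = run$selections[[nm]]$gene), paste0("selected_gene_", nm, ".tsv"))
    wt(data.frame(feature_id = run$selections[[nm]]$exon), paste0("selected_exon_", nm, ".tsv"))
  }
  if (!is.null(run$enrichment)) wt(run$enrichment, "enrichment.tsv")
  if (!is.null(run$structure$gene_sample_tree)) {
    p <- file.path(out_dir, "gene_sample_tree.nwk")
    writeLines(as_newick(run$structure$gene_sample_tree), p)
    files[["gene_sample_tree.nwk"]] <- p
  }
  wt(data.frame(sample_id = rownames(run$structure$pca$scores),
                run$structure$pca$scores, check.names = FALSE),
     "pca_scores.tsv")

  manifest <- list(
    parameters = serialize_config(run$config),
    counts = as.list(run$detection$counts),
    n_detectable_clusters = length(run$detection$detectable_cluster_ids),
    selected = lapply(run$selections, function(s)
      list(gene = length(s$gene), exon = length(s$exon))),
    files = lapply(files, function(p) unname(tools::md5sum(p))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  run$manifest <- manifest
  run
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$criteria <- unclass(out$criteria)
  out$gene_sets <- if (!is.null(out$gene_sets)) length(out$gene_sets)
  if (!is.null(out$sim)) {
    sim <- unclass(out$sim)
    sim$de_spikes <- if (!is.null(sim$de_spikes)) nrow(sim$de_spikes) else 0L
    sim$splice_spikes <- if (!is.null(sim$splice_spikes)) nrow(sim$splice_spikes) else 0L
    sim$group_sizes <- as.list(sim$group_sizes)
    out$sim <- sim
  }
  out
}

#' @export
print.exonsplice_run <- function(x, ...) {
  cat("exonsplice_run\n")
  cat("  detection ladder:",
      paste(sprintf("%s=%d", names(x$detection$counts), x$detection$counts),
            collapse = " -> "),
      sprintf("(%d detectable clusters)\n",
              length(x$detection$detectable_cluster_ids)))
  for (nm in names(x$selections)) {
    cat(sprintf("  %s: %d genes DE, %d exons spliced\n", nm,
                length(x$selections[[nm]]$gene), length(x$selections[[nm]]$exon)))
  }
  for (nm in names(x$setops$overlap)) {
    o <- x$setops$overlap[[nm]]
    cat(sprintf("  overlap %s: %d/%d spliced genes also DE (%s%%)\n", nm,
                o$count_both, o$n_spliced,
                if (is.na(o$percent)) "NA" else format(o$percent)))
  }
  if (!is.null(x$evaluation)) {
    for (nm in names(x$evaluation)) {
      ev <- x$evaluation[[nm]]
      cat(sprintf("  truth %s: splice sens %.2f prec %.2f | DE sens %.2f prec %.2f\n",
                  nm, ev$splice_sensitivity, ev$splice_precision,
                  ev$de_sensitivity, ev$de_precision))
    }
  }
  invisible(x)
}

#' @export
summary.exonsplice_run <- function(object, ...) {
  print(object)
  if (!is.null(object$enrichment)) {
    cat("  top enriched sets:\n")
    top <- object$enrichment[order(object$enrichment$p), ]
    print(utils::head(top, 5L))
  }
  invisible(object)
}
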