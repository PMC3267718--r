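# Synthetic exon-array generator with known truth. Probe intensities follow
#   2^(baseline + cluster effect + probe-set offset + probe affinity
#      + group effects + noise) + GC-dependent background
# so every downstream stage (DABG, RMA, splicing index, selection) has
# genuine structure to recover: non-expressed clusters emit background only,
# whole-gene spikes shift all probes of a cluster in one group, and splicing
# spikes shift one exon while compensating its siblings so the cluster's mean
# log2 effect — the gene-level truth — is untouched.

#' Simulation configuration
#'
#' Defaults mirror the array design of the neonatal HLHS ventricle study this
#' pipeline models: three groups of 6/5/5 samples and roughly 40 probes per
#' gene organized as 10 exon probe sets of 4 probes each.
#'
#' @param n_clusters number of transcript clusters (genes).
#' @param exon_probesets_per_cluster scalar, or length-2 range sampled per
#'   cluster.
#' @param probes_per_probeset probes per exon probe set (4 on the exon array).
#' @param group_sizes named integer vector, group -> number of samples.
#' @param baseline_log2_mean grand mean log2 signal of expressed genes.
#' @param cluster_sd sd of per-cluster log2 abundance.
#' @param probeset_sd sd of per-probe-set log2 offsets (exon usage baseline).
#' @param affinity_sd sd of fixed per-probe affinities (shared across
#'   samples; the structure median polish removes).
#' @param probe_noise_sd sd of per-observation log2 noise.
#' @param frac_nonexpressed fraction of clusters emitting background only.
#' @param de_spikes `data.frame(cluster_id, group, log2_fold)`: whole-gene
#'   log2 shifts applied to one group's mean.
#' @param splice_spikes `data.frame(probeset_id, group, log2_fold)`:
#'   exon-specific shifts, mean-balanced within the cluster (see
#'   [spike_splicing_balanced()]); set `balanced = FALSE` for raw shifts.
#' @param balanced balance splicing spikes within cluster (default `TRUE`).
#' @param n_background_probes number of genomic background probes.
#' @param bg_log2_intercept,bg_gc_slope background mean log2 intensity is
#'   `bg_log2_intercept + bg_gc_slope * gc`, giving DABG a real GC effect.
#' @param bg_sd sd of background log2 intensity.
#' @param seed integer seed; mandatory, every draw is derived from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 50L,
                       exon_probesets_per_cluster = 10L,
                       probes_per_probeset = 4L,
                       group_sizes = c(HLHS_RV = 6L, Control_RV = 5L, Control_LV = 5L),
                       baseline_log2_mean = 8,
                       cluster_sd = 1.5,
                       probeset_sd = 0.5,
                       affinity_sd = 0.7,
                       probe_noise_sd = 0.25,
                       frac_nonexpressed = 0.2,
                       de_spikes = NULL,
                       splice_spikes = NULL,
                       balanced = TRUE,
                       n_background_probes = 2000L,
                       bg_log2_intercept = 4,
                       bg_gc_slope = 2,
                       bg_sd = 0.5,
                       seed) {
  if (missing(seed) || is.null(seed)) stop_schema("sim_config: seed is mandatory")
  cfg <- list(n_clusters = as.integer(n_clusters),
              exon_probesets_per_cluster = as.integer(exon_probesets_per_cluster),
              probes_per_probeset = as.integer(probes_per_probeset),
              group_sizes = group_sizes,
              baseline_log2_mean = baseline_log2_mean,
              cluster_sd = cluster_sd, probeset_sd = probeset_sd,
              affinity_sd = affinity_sd, probe_noise_sd = probe_noise_sd,
              frac_nonexpressed = frac_nonexpressed,
              de_spikes = de_spikes, splice_spikes = splice_spikes,
              balanced = isTRUE(balanced),
              n_background_probes = as.integer(n_background_probes),
              bg_log2_intercept = bg_log2_intercept,
              bg_gc_slope = bg_gc_slope, bg_sd = bg_sd,
              seed = as.integer(seed))
  stopifnot(cfg$n_clusters >= 1L, cfg$probes_per_probeset >= 1L,
            all(cfg$exon_probesets_per_cluster >= 1L),
            length(cfg$exon_probesets_per_cluster) %in% 1:2,
            cfg$n_background_probes >= 1L)
  if (cfg$frac_nonexpressed < 0 || cfg$frac_nonexpressed > 1) {
    stop_schema("frac_nonexpressed must be in [0, 1]")
  }
  if (is.null(names(cfg$group_sizes)) || any(!nzchar(names(cfg$group_sizes)))) {
    stop_schema("group_sizes must be a named vector")
  }
  for (sp in list(cfg$de_spikes, cfg$splice_spikes)) {
    if (!is.null(sp) && any(!is.finite(sp$log2_fold))) {
      stop_schema("spike log2 folds must be finite")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Balanced splicing-spike offsets
#'
#' Distributes an exon-specific log2 shift over the probe sets of a cluster
#' so the cluster's mean log2 effect (the gene-level truth) is unchanged: the
#' target probe set moves by `+log2_fold`, each of the `m - 1` siblings by
#' `-log2_fold / (m - 1)`.
#'
#' @param n_probesets number of exon probe sets in the cluster (>= 2).
#' @param target_index position of the spiked probe set.
#' @param log2_fold exon-specific log2 shift.
#' @return numeric vector of per-probe-set offsets summing to zero.
#' @export
#' @examples
#' spike_splicing_balanced(4, 1, 2)  # c(2, -2/3, -2/3, -2/3)
spike_splicing_balanced <- function(n_probesets, target_index, log2_fold) {
  if (n_probesets < 2L) {
    stop_schema("splicing is undefined for a single-exon cluster")
  }
  if (target_index < 1L || target_index > n_probesets) {
    stop_schema("target_index out of range")
  }
  off <- rep(-log2_fold / (n_probesets - 1L), n_probesets)
  off[target_index] <- log2_fold
  off
}

#' Simulate a probe-level exon-array dataset with known truth
#'
#' @param config a [sim_config()].
#' @return list of class `exonsplice_sim` with elements
#'   `probes` (linear-scale probe x sample matrix, probe ids
#'   `<probeset>:<k>`), `annotation`, `design`, `background` (background-probe
#'   matrix with a `gc_fraction` attribute), `truth` (per-cluster expressed
#'   flags and true DE log2 folds, per-probe-set true splicing log2 folds,
#'   per comparison against the first group), and `config`.
#' @export
simulate_exon_array <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- names(config$group_sizes)

  cluster_ids <- sprintf("TC%04d", seq_len(config$n_clusters))
  n_ps <- if (length(config$exon_probesets_per_cluster) == 1L) {
    rep(config$exon_probesets_per_cluster, config$n_clusters)
  } else {
    sample(seq(config$exon_probesets_per_cluster[1L],
               config$exon_probesets_per_cluster[2L]),
           config$n_clusters, replace = TRUE)
  }
  ps_cluster <- rep(cluster_ids, n_ps)
  ps_index <- unlist(lapply(n_ps, seq_len), use.names = FALSE)
  probeset_ids <- sprintf("%s_PS%02d", ps_cluster, ps_index)
  gc <- stats::runif(length(probeset_ids), 0.25, 0.75)

  annotation <- data.frame(probeset_id = probeset_ids,
                           transcript_cluster_id = ps_cluster,
                           n_probes = config$probes_per_probeset,
                           level = "core",
                           cross_hyb = FALSE,
                           exon_index = ps_index,
                           gc_fraction = gc,
                           stringsAsFactors = FALSE)

  design <- data.frame(
    sample_id = unlist(lapply(groups, function(g) {
      sprintf("%s_%02d", g, seq_len(config$group_sizes[[g]]))
    }), use.names = FALSE),
    group = rep(groups, config$group_sizes),
    stringsAsFactors = FALSE)
  n_samples <- nrow(design)

  # spiked clusters must be expressed; draw the non-expressed set from the rest
  spiked_cl <- unique(c(config$de_spikes$cluster_id,
                        ps_cluster[match(config$splice_spikes$probeset_id,
                                         probeset_ids)]))
  expressed <- rep(TRUE, config$n_clusters)
  n_off <- round(config$frac_nonexpressed * config$n_clusters)
  eligible <- which(!cluster_ids %in% spiked_cl)
  if (n_off > length(eligible)) {
    stop_schema("spike references a non-expressed cluster: frac_nonexpressed = ",
                config$frac_nonexpressed, " leaves fewer than ", n_off,
                " unspiked clusters")
  }
  if (n_off > 0L) expressed[sample(eligible, n_off)] <- FALSE
  names(expressed) <- cluster_ids

  cluster_eff <- stats::rnorm(config$n_clusters, 0, config$cluster_sd)
  names(cluster_eff) <- cluster_ids
  ps_offset <- stats::rnorm(length(probeset_ids), 0, config$probeset_sd)

  # group-effect matrices; DE spikes act at cluster level, splicing spikes at
  # probe-set level (mean-balanced within cluster unless balanced = FALSE)
  cl_group <- matrix(0, config$n_clusters, length(groups),
                     dimnames = list(cluster_ids, groups))
  if (!is.null(config$de_spikes)) {
    for (i in seq_len(nrow(config$de_spikes))) {
      sp <- config$de_spikes[i, ]
      if (!sp$cluster_id %in% cluster_ids) {
        stop_schema("de_spike references unknown cluster ", sp$cluster_id)
      }
      if (!expressed[[sp$cluster_id]]) {
        stop_schema("de_spike references non-expressed cluster ", sp$cluster_id)
      }
      cl_group[sp$cluster_id, sp$group] <- cl_group[sp$cluster_id, sp$group] + sp$log2_fold
    }
  }
  ps_group <- matrix(0, length(probeset_ids), length(groups),
                     dimnames = list(probeset_ids, groups))
  if (!is.null(config$splice_spikes)) {
    for (i in seq_len(nrow(config$splice_spikes))) {
      sp <- config$splice_spikes[i, ]
      if (!sp$probeset_id %in% probeset_ids) {
        stop_schema("splice_spike references unknown probe set ", sp$probeset_id)
      }
      cl <- ps_cluster[match(sp$probeset_id, probeset_ids)]
      if (!expressed[[cl]]) {
        stop_schema("splice_spike references non-expressed cluster ", cl)
      }
      members <- which(ps_cluster == cl)
      if (config$balanced) {
        off <- spike_splicing_balanced(length(members),
                                       match(sp$probeset_id, probeset_ids[members]),
                                       sp$log2_fold)
      } else {
        off <- rep(0, length(members))
        off[match(sp$probeset_id, probeset_ids[members])] <- sp$log2_fold
      }
      ps_group[members, sp$group] <- ps_group[members, sp$group] + off
    }
  }

  # probe-level assembly
  n_probes <- length(probeset_ids) * config$probes_per_probeset
  probe_ps <- rep(probeset_ids, each = config$probes_per_probeset)
  probe_ids <- paste0(probe_ps, ":", seq_len(config$probes_per_probeset))
  probe_row <- match(probe_ps, probeset_ids)
  probe_cl_row <- match(ps_cluster[probe_row], cluster_ids)
  affinity <- stats::rnorm(n_probes, 0, config$affinity_sd)
  probe_gc <- gc[probe_row]

  g_of_sample <- match(design$group, groups)
  mu <- config$baseline_log2_mean + cluster_eff[probe_cl_row] +
    ps_offset[probe_row] + affinity
  signal_log2 <- outer(mu, rep(0, n_samples), `+`) +
    cl_group[cbind(rep(probe_cl_row, n_samples), rep(g_of_sample, each = n_probes))] +
    ps_group[cbind(rep(probe_row, n_samples), rep(g_of_sample, each = n_probes))] +
    stats::rnorm(n_probes * n_samples, 0, config$probe_noise_sd)
  bg_draw <- 2 ^ stats::rnorm(n_probes * n_samples,
                              config$bg_log2_intercept + config$bg_gc_slope * probe_gc,
                              config$bg_sd)
  on <- as.numeric(expressed[probe_cl_row])  # recycled down columns
  probes <- (2 ^ signal_log2) * on + bg_draw
  dim(probes) <- c(n_probes, n_samples)
  dimnames(probes) <- list(probe_ids, design$sample_id)

  bg_gc <- stats::runif(config$n_background_probes, 0, 1)
  background <- matrix(
    2 ^ stats::rnorm(config$n_background_probes * n_samples,
                     config$bg_log2_intercept + config$bg_gc_slope * bg_gc,
                     config$bg_sd),
    config$n_background_probes, n_samples,
    dimnames = list(sprintf("BG%05d", seq_len(config$n_background_probes)),
                    design$sample_id))
  attr(background, "gc_fraction") <- bg_gc

  # truth relative to the first (case) group versus each other group
  ref <- groups[1L]
  comparisons <- paste0(ref, "_vs_", groups[-1L])
  cl_truth <- data.frame(cluster_id = cluster_ids, expressed = unname(expressed),
                         de_spiked = cluster_ids %in% config$de_spikes$cluster_id,
                         stringsAsFactors = FALSE)
  ps_truth <- data.frame(probeset_id = probeset_ids,
                         transcript_cluster_id = ps_cluster,
                         splice_spiked = probeset_ids %in% config$splice_spikes$probeset_id,
                         stringsAsFactors = FALSE)
  for (j in seq_along(comparisons)) {
    other <- groups[-1L][j]
    cl_truth[[paste0("log2_fold_", comparisons[j])]] <-
      cl_group[, ref] - cl_group[, other] +
      as.vector(rowsum(ps_group[, ref] - ps_group[, other], ps_cluster,
                       reorder = FALSE)) / n_ps
    ps_truth[[paste0("splice_log2_fold_", comparisons[j])]] <-
      ps_group[, ref] - ps_group[, other]
  }

  structure(list(probes = structure(probes, level = "probe", scale = "linear"),
                 annotation = annotation, design = design,
                 background = background,
                 truth = list(clusters = cl_truth, probesets = ps_truth,
                              comparisons = comparisons),
                 config = config),
            class = "exonsplice_sim")
}

#' @export
print.exonsplice_sim <- function(x, ...) {
  cat("exonsplice_sim:", nrow(x$probes), "probes /",
      nrow(x$annotation), "probe sets /",
      length(unique(x$annotation$transcript_cluster_id)), "clusters;",
      nrow(x$design), "samples (", paste(table(x$design$group), collapse = "/"),
      ");", sum(!x$truth$clusters$expressed), "non-expressed clusters\n")
  invisible(x)
}
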