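# Detection filtering and RMA-style preprocessing.
#
# DABG (detection above background): each probe's intensity is ranked against
# GC-matched genomic background probes, giving an empirical p-value; probe
# p-values are combined per probe set by Fisher's method. Detection then runs
# as a two-step cascade — exon probe sets first, transcript clusters second —
# followed by reconciliation against the gene-level summarized matrix.
#
# RMA: convolution background correction (exponential signal + normal
# background), quantile normalization across arrays at probe level, log2,
# then per-probe-set / per-cluster two-way median polish.

# ---- DABG -------------------------------------------------------------------

gc_bin_of <- function(gc, gc_bins) {
  pmin(floor(gc * gc_bins) + 1L, gc_bins)
}

#' Detection-above-background p-values
#'
#' For every probe and sample, the empirical p-value is
#' `(1 + #\{background probes in the same GC bin with intensity >= probe\}) /
#' (1 + bin size)`; probe p-values are combined per probe set with Fisher's
#' method (chi-square with `2k` df for `k` probes). GC bins partition `[0,1]`
#' into `gc_bins` equal-width intervals.
#'
#' @param probe_matrix linear-scale probe x sample matrix; probe ids follow
#'   the `<probeset>:<k>` convention (see [probe_probeset()]).
#' @param background_matrix background-probe x sample matrix.
#' @param annotation probe-set annotation carrying `gc_fraction`.
#' @param gc_bins number of equal-width GC bins (default 4).
#' @param bg_gc GC fraction of each background probe; defaults to the
#'   matrix's `gc_fraction` attribute.
#' @return probe-set x sample matrix of p-values in (0, 1].
#' @export
compute_dabg <- function(probe_matrix, background_matrix, annotation,
                         gc_bins = 4L,
                         bg_gc = attr(background_matrix, "gc_fraction")) {
  if (is.null(bg_gc)) stop_schema("background probes must carry gc_fraction")
  stopifnot(length(bg_gc) == nrow(background_matrix),
            identical(colnames(probe_matrix), colnames(background_matrix)))
  ps_of_probe <- probe_probeset(rownames(probe_matrix))
  hit <- match(ps_of_probe, annotation$probeset_id)
  if (anyNA(hit)) {
    stop_schema("probes mapping to probe sets absent from annotation: ",
                paste(utils::head(unique(ps_of_probe[is.na(hit)]), 5L), collapse = ", "))
  }
  probe_bin <- gc_bin_of(annotation$gc_fraction[hit], gc_bins)
  bg_bin <- gc_bin_of(bg_gc, gc_bins)
  used <- sort(unique(probe_bin))
  empty <- setdiff(used, unique(bg_bin))
  if (length(empty)) {
    stop_schema("no background probes in GC bin(s) ",
                paste(empty, collapse = ", "), " of ", gc_bins)
  }

  p_probe <- matrix(NA_real_, nrow(probe_matrix), ncol(probe_matrix),
                    dimnames = dimnames(probe_matrix))
  for (b in used) {
    tr <- which(probe_bin == b)
    br <- which(bg_bin == b)
    nb <- length(br)
    for (s in seq_len(ncol(probe_matrix))) {
      bg_sorted <- sort(background_matrix[br, s])
      # findInterval(x, v, left.open = TRUE) counts background values < x,
      # so nb minus it counts background values >= x (ties included)
      n_ge <- nb - findInterval(probe_matrix[tr, s], bg_sorted, left.open = TRUE)
      p_probe[tr, s] <- (1 + n_ge) / (1 + nb)
    }
  }

  k <- table(factor(ps_of_probe, levels = unique(ps_of_probe)))
  if (any(k == 0L)) stop_schema("probe set with zero probes")
  fisher_stat <- rowsum(-2 * log(p_probe), group = ps_of_probe, reorder = FALSE)
  p_set <- stats::pchisq(fisher_stat, df = 2 * as.vector(k[rownames(fisher_stat)]),
                         lower.tail = FALSE)
  pmax(p_set, .Machine$double.xmin)
}

# ---- detection cascade ------------------------------------------------------

#' Step 1: per-probe-set detection across groups
#'
#' A probe set is detected when, in at least one treatment group, the
#' fraction of that group's samples with DABG p below `alpha` reaches
#' `min_fraction`. The default comparator is `>=` ("at least half the samples
#' of some group"); a strict `>` is available for symmetry with step 2.
#'
#' @param dabg_p probe-set x sample DABG p-value matrix.
#' @param design sample design table.
#' @param alpha DABG significance cut-off (default 0.05).
#' @param min_fraction required within-group detected fraction (default 0.5).
#' @param comparator `">="` (default) or `">"`.
#' @return named logical vector, one verdict per probe set.
#' @export
detect_exon_probesets <- function(dabg_p, design, alpha = 0.05,
                                  min_fraction = 0.5,
                                  comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  cols <- group_columns(design, colnames(dabg_p))
  frac <- sapply(cols, function(j) rowMeans(dabg_p[, j, drop = FALSE] < alpha))
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = 1L, dimnames = list(rownames(dabg_p)))
  hit <- if (comparator == ">=") frac >= min_fraction else frac > min_fraction
  out <- rowSums(hit) > 0L
  names(out) <- rownames(dabg_p)
  out
}

#' Step 2: transcript-cluster detection
#'
#' A cluster is detected when the fraction of its member exon probe sets
#' detected in step 1 exceeds `min_fraction` (strictly, by default: a cluster
#' with exactly half its exons detected is not called).
#'
#' @param exon_detected named logical vector from [detect_exon_probesets()].
#' @param annotation probe-set annotation (maps probe sets to clusters).
#' @param min_fraction required detected-member fraction (default 0.5).
#' @param comparator `">"` (default, strict) or `">="`.
#' @return named logical vector, one verdict per cluster.
#' @export
detect_transcript_clusters <- function(exon_detected, annotation,
                                       min_fraction = 0.5,
                                       comparator = c(">", ">=")) {
  comparator <- match.arg(comparator)
  hit <- match(names(exon_detected), annotation$probeset_id)
  if (anyNA(hit)) {
    stop_schema("probe sets absent from annotation: ",
                paste(utils::head(names(exon_detected)[is.na(hit)], 5L), collapse = ", "))
  }
  cl <- annotation$transcript_cluster_id[hit]
  n <- table(factor(cl, levels = unique(cl)))
  if (any(n == 0L)) stop_schema("cluster with no member probe sets")
  frac <- as.vector(rowsum(as.numeric(exon_detected), cl, reorder = FALSE)) /
    as.vector(n[unique(cl)])
  out <- if (comparator == ">") frac > min_fraction else frac >= min_fraction
  names(out) <- unique(cl)
  out
}

#' Reconcile detection verdicts with the gene-level output
#'
#' The final detectable exon probe sets are those detected in step 1 whose
#' cluster is detected in step 2 *and* present in the gene-level summarized
#' matrix (clusters can drop out of gene-level summarization); the final
#' detectable clusters are the detected clusters present in the gene-level
#' matrix with at least one detectable exon. Stage counts (input, step 1,
#' step 2, reconciled) are logged.
#'
#' @param exon_detected,cluster_detected verdict vectors from the two steps.
#' @param gene_matrix gene-level matrix whose row names are cluster ids.
#' @param annotation probe-set annotation.
#' @return list with `detectable_exon_ids`, `detectable_cluster_ids`, and a
#'   named integer `counts` ladder.
#' @export
reconcile_detectable <- function(exon_detected, cluster_detected, gene_matrix,
                                 annotation) {
  cl_of <- annotation$transcript_cluster_id[match(names(exon_detected),
                                                  annotation$probeset_id)]
  step1 <- names(exon_detected)[exon_detected]
  in_detected_cluster <- cluster_detected[cl_of]
  step2 <- names(exon_detected)[exon_detected & !is.na(in_detected_cluster) &
                                  in_detected_cluster]
  cl_of_step2 <- cl_of[match(step2, names(exon_detected))]
  present <- cl_of_step2 %in% rownames(gene_matrix)
  detectable_exon_ids <- step2[present]
  detectable_cluster_ids <- intersect(
    names(cluster_detected)[cluster_detected],
    unique(cl_of_step2[present]))
  counts <- c(input = length(exon_detected), step1 = length(step1),
              step2 = length(step2), reconciled = length(detectable_exon_ids))
  es_log("detection ladder: input ", counts[["input"]], " -> step1 ",
         counts[["step1"]], " -> step2 ", counts[["step2"]], " -> reconciled ",
         counts[["reconciled"]], " exon probe sets; ",
         length(detectable_cluster_ids), " detectable clusters")
  if (length(detectable_exon_ids) == 0L) {
    warning("no detectable exon probe sets after reconciliation", call. = FALSE)
  }
  list(detectable_exon_ids = detectable_exon_ids,
       detectable_cluster_ids = detectable_cluster_ids,
       counts = counts)
}

# ---- RMA --------------------------------------------------------------------

#' RMA convolution background parameters and adjustment
#'
#' The convolution model takes each observed intensity as signal plus
#' background, signal ~ Exponential(`alpha`), background ~ Normal(`mu`,
#' `sigma`). `rma_bg_params` estimates the parameters per array with the
#' mode-based heuristic (background mean at the density mode, spread from the
#' points below the mode with a half-normal correction, signal rate from the
#' mean exceedance above the mode); `rma_bg_adjust` returns the closed-form
#' conditional expectation E[signal | observed], which is strictly positive.
#'
#' @param x numeric vector of one array's linear-scale intensities.
#' @return `rma_bg_params`: list with `mu`, `sigma`, `alpha`.
#' @export
rma_bg_params <- function(x) {
  if (length(unique(x)) < 3L) {
    stop_schema("degenerate background: (nearly) constant array")
  }
  density_mode <- function(v) {
    d <- stats::density(v, kernel = "epanechnikov", n = 2^12)
    d$x[which.max(d$y)]
  }
  # two-pass mode search: the global mode of a skewed intensity distribution
  # overshoots the background peak, so it is refined on the sub-mode points
  mode <- density_mode(x)
  if (sum(x < mode) >= 3L) mode <- density_mode(x[x < mode])
  below <- x[x < mode]
  above <- x[x > mode]
  if (length(below) < 2L || length(above) < 2L) {
    stop_schema("degenerate background: no spread around the intensity mode")
  }
  # left tail is half-normal around the mode: double its mean square
  sigma <- sqrt(sum((below - mode)^2) / (length(below) - 1)) * sqrt(2)
  alpha <- 1 / mean(above - mode)
  list(mu = mode, sigma = sigma, alpha = alpha)
}

#' @rdname rma_bg_params
#' @param mu,sigma background normal mean and sd.
#' @param alpha signal exponential rate.
#' @export
rma_bg_adjust <- function(x, mu, sigma, alpha) {
  a <- x - mu - sigma^2 * alpha
  b <- (x - a) / sigma  # = (mu + sigma^2 alpha) / sigma, constant
  num <- stats::dnorm(a / sigma) - stats::dnorm(b)
  den <- stats::pnorm(a / sigma) + stats::pnorm(b) - 1
  out <- a + sigma * num / pmax(den, 1e-300)
  pmax(out, 2^-20)  # conditional mean of a positive variable; guard roundoff
}

#' @rdname rma_bg_params
#' @param probe_matrix linear-scale probe x sample matrix.
#' @return `background_correct`: matrix of the same shape, strictly positive.
#' @export
background_correct <- function(probe_matrix) {
  out <- probe_matrix
  for (s in seq_len(ncol(probe_matrix))) {
    pars <- rma_bg_params(probe_matrix[, s])
    out[, s] <- rma_bg_adjust(probe_matrix[, s], pars$mu, pars$sigma, pars$alpha)
  }
  out
}

#' Quantile normalization
#'
#' Forces every column onto the common quantile profile: the i-th smallest
#' value of each column becomes the mean of the i-th smallest values across
#' columns. Ties within a column receive the mean of the reference values
#' their ranks span, which makes the transform idempotent.
#'
#' @param mat numeric matrix with >= 2 columns and no missing values.
#' @return normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(mat) {
  if (anyNA(mat)) stop_schema("quantile_normalize: missing values")
  if (ncol(mat) < 2L) {
    warning("single column: quantile normalization is a no-op", call. = FALSE)
    return(mat)
  }
  ref <- rowMeans(apply(mat, 2L, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    o <- order(mat[, j])
    sorted <- mat[o, j]
    vals <- ref
    r <- rle(sorted)
    if (any(r$lengths > 1L)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in which(r$lengths > 1L)) {
        vals[starts[i]:ends[i]] <- mean(ref[starts[i]:ends[i]])
      }
    }
    out[o, j] <- vals
  }
  out
}

#' Two-way median polish
#'
#' Tukey's median polish of a probes x samples block: alternately sweeps row
#' and column medians into row/column effects until the total absolute
#' residual changes by less than `tol` (or `maxiter` sweeps). The per-sample
#' summary is `overall + column effect`, which is invariant to per-row
#' (probe-affinity) shifts.
#'
#' @param x numeric matrix.
#' @param maxiter maximum sweeps (default 10, the classic RMA setting).
#' @param tol absolute convergence tolerance on the residual L1 norm.
#' @return list with `overall`, `row`, `col`, `residuals`, `converged`.
#' @export
median_polish <- function(x, maxiter = 10L, tol = 0.01) {
  x <- as.matrix(x)
  t0 <- 0
  r <- rep(0, nrow(x))
  cl <- rep(0, ncol(x))
  resid <- x
  oldsum <- 0
  converged <- FALSE
  for (iter in seq_len(maxiter)) {
    rdelta <- apply(resid, 1L, stats::median)
    resid <- resid - rdelta
    r <- r + rdelta
    delta <- stats::median(cl)
    cl <- cl - delta
    t0 <- t0 + delta
    cdelta <- apply(resid, 2L, stats::median)
    resid <- resid - rep(cdelta, each = nrow(x))
    cl <- cl + cdelta
    delta <- stats::median(r)
    r <- r - delta
    t0 <- t0 + delta
    newsum <- sum(abs(resid))
    if (newsum == 0 || abs(newsum - oldsum) < tol) {
      converged <- TRUE
      break
    }
    oldsum <- newsum
  }
  list(overall = t0, row = r, col = cl, residuals = resid, converged = converged)
}

#' Median-polish summarization to exon or gene level
#'
#' Groups log2 probe intensities by exon probe set or by transcript cluster
#' and summarizes each block with [median_polish()]; the summary for sample
#' `j` is `overall + col[j]`. Blocks keep the annotation's order.
#'
#' @param probe_log2 log2-scale probe x sample matrix.
#' @param annotation probe-set annotation.
#' @param target_level `"exon_probeset"` or `"transcript_cluster"`.
#' @param maxiter,tol passed to [median_polish()].
#' @return feature x sample matrix tagged with `level` and `scale = "log2"`.
#' @export
median_polish_summarize <- function(probe_log2, annotation,
                                    target_level = c("exon_probeset", "transcript_cluster"),
                                    maxiter = 10L, tol = 0.01) {
  target_level <- match.arg(target_level)
  ps <- probe_probeset(rownames(probe_log2))
  key <- if (target_level == "exon_probeset") {
    ps
  } else {
    annotation$transcript_cluster_id[match(ps, annotation$probeset_id)]
  }
  if (anyNA(key)) stop_schema("probes with no annotation entry")
  lev <- if (target_level == "exon_probeset") {
    unique(annotation$probeset_id[annotation$probeset_id %in% key])
  } else {
    unique(annotation$transcript_cluster_id[annotation$transcript_cluster_id %in% key])
  }
  rows <- split(seq_len(nrow(probe_log2)), factor(key, levels = lev))
  out <- matrix(NA_real_, length(lev), ncol(probe_log2),
                dimnames = list(lev, colnames(probe_log2)))
  for (i in seq_along(rows)) {
    block <- probe_log2[rows[[i]], , drop = FALSE]
    if (nrow(block) == 1L) {
      out[i, ] <- block  # degenerate single-probe group: summary is the value
    } else {
      mp <- median_polish(block, maxiter = maxiter, tol = tol)
      out[i, ] <- mp$overall + mp$col
    }
  }
  structure(out, level = target_level, scale = "log2")
}

#' Full RMA-style preprocessing
#'
#' Convolution background correction per array, quantile normalization across
#' arrays at probe level, log2 transform, then median-polish summarization at
#' the requested level.
#'
#' @param probe_matrix linear-scale probe x sample matrix.
#' @param annotation probe-set annotation.
#' @param target_level `"exon_probeset"` or `"transcript_cluster"`.
#' @param bg_correct apply the convolution correction (default TRUE).
#' @return log2 feature x sample matrix.
#' @export
rma_summarize <- function(probe_matrix, annotation,
                          target_level = c("exon_probeset", "transcript_cluster"),
                          bg_correct = TRUE) {
  target_level <- match.arg(target_level)
  m <- if (isTRUE(bg_correct)) background_correct(probe_matrix) else probe_matrix
  m <- quantile_normalize(m)
  median_polish_summarize(log2(m), annotation, target_level = target_level)
}
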