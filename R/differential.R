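# Splicing index, fold changes, row-wise ANOVA / t-tests, Benjamini-Hochberg
# FDR and the compound selection rule.
#
# The splicing index of an exon in a sample is
#   SI = log2(exon-level intensity) - log2(gene-level intensity of its cluster),
# i.e. the exon's abundance relative to its own gene; group differences in SI
# indicate differential exon inclusion independent of whole-gene expression.

#' Splicing-index matrix
#'
#' @param exon_log2 log2 exon-probe-set x sample matrix.
#' @param gene_log2 log2 transcript-cluster x sample matrix with the same
#'   sample order.
#' @param annotation probe-set annotation mapping exons to clusters.
#' @return exon x sample matrix of log2 ratios (`SI`).
#' @export
splicing_index <- function(exon_log2, gene_log2, annotation) {
  if (!identical(colnames(exon_log2), colnames(gene_log2))) {
    stop_schema("exon and gene matrices must share sample order")
  }
  cl <- annotation$transcript_cluster_id[match(rownames(exon_log2),
                                               annotation$probeset_id)]
  orphan <- is.na(cl) | !(cl %in% rownames(gene_log2))
  if (any(orphan)) {
    stop_schema("exons whose cluster is missing from the gene-level matrix: ",
                paste(utils::head(rownames(exon_log2)[orphan], 5L), collapse = ", "))
  }
  si <- exon_log2 - gene_log2[cl, , drop = FALSE]
  dimnames(si) <- dimnames(exon_log2)
  structure(si, scale = "log2_ratio")
}

#' Linear fold change between two groups
#'
#' `2 ^ (mean log2 in group_a - mean log2 in group_b)`, reported as-is:
#' values below 1 denote down-regulation in `group_a` (a gene at 0.3 is about
#' 3.3-fold down), never folded to be >= 1.
#'
#' @param mat log2 feature x sample matrix (or splicing-index matrix).
#' @param design sample design.
#' @param group_a numerator group (the case group by convention).
#' @param group_b denominator group.
#' @return named numeric vector of linear ratios.
#' @export
fold_change <- function(mat, design, group_a, group_b) {
  cols <- group_columns(design, colnames(mat))
  for (g in c(group_a, group_b)) {
    if (!g %in% names(cols)) stop_schema("group absent from design: ", g)
    if (length(cols[[g]]) < 1L) stop_schema("empty group: ", g)
  }
  2 ^ (rowMeans(mat[, cols[[group_a]], drop = FALSE]) -
         rowMeans(mat[, cols[[group_b]], drop = FALSE]))
}

#' Row-wise one-way fixed-effects ANOVA
#'
#' The classic F statistic with (k - 1, N - k) degrees of freedom, computed
#' for every feature at once. Features with zero within-group variance are
#' flagged degenerate: p = 0 when group means differ, undefined (NA) when the
#' feature is constant; degenerate features are meant to be excluded from
#' FDR adjustment.
#'
#' @param mat feature x sample matrix.
#' @param design sample design with >= 2 groups of >= 2 samples.
#' @return `data.frame` with `F`, `p`, `df1`, `df2`, `degenerate`.
#' @export
row_oneway_anova <- function(mat, design) {
  cols <- group_columns(design, colnames(mat))
  if (length(cols) < 2L) stop_schema("ANOVA needs >= 2 groups")
  if (any(lengths(cols) < 2L)) stop_schema("every group needs >= 2 samples")
  N <- ncol(mat)
  k <- length(cols)
  grand <- rowMeans(mat)
  ssb <- 0
  ssw <- 0
  for (j in cols) {
    gm <- rowMeans(mat[, j, drop = FALSE])
    ssb <- ssb + length(j) * (gm - grand)^2
    ssw <- ssw + rowSums((mat[, j, drop = FALSE] - gm)^2)
  }
  df1 <- k - 1L
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  degenerate <- ssw == 0
  f[degenerate & ssb > 0] <- Inf
  p[degenerate & ssb > 0] <- 0
  f[degenerate & ssb == 0] <- NA_real_
  p[degenerate & ssb == 0] <- NA_real_
  data.frame(F = f, p = p, df1 = df1, df2 = df2, degenerate = degenerate,
             row.names = rownames(mat))
}

#' Row-wise two-group t-tests
#'
#' Pooled-variance (default), Welch, or empirical-Bayes moderated t. The
#' moderated variant shrinks each feature's pooled variance toward a common
#' prior `s0^2` with prior df `d0`, both estimated from the across-feature
#' variance distribution by moment matching against the scaled-F sampling
#' model (`s^2 / s0^2 ~ F(d, d0)`); the moderated statistic has `d + d0` df.
#'
#' @param mat feature x sample matrix.
#' @param design sample design.
#' @param group_a,group_b the two groups ( >= 2 samples each).
#' @param variant `"pooled"`, `"welch"` or `"moderated"`.
#' @return `data.frame` with `t`, `p`, `df`, `degenerate`.
#' @export
two_group_test <- function(mat, design, group_a, group_b,
                           variant = c("pooled", "welch", "moderated")) {
  variant <- match.arg(variant)
  cols <- group_columns(design, colnames(mat))
  for (g in c(group_a, group_b)) {
    if (!g %in% names(cols)) stop_schema("group absent from design: ", g)
    if (length(cols[[g]]) < 2L) stop_schema("group needs >= 2 samples: ", g)
  }
  xa <- mat[, cols[[group_a]], drop = FALSE]
  xb <- mat[, cols[[group_b]], drop = FALSE]
  na <- ncol(xa)
  nb <- ncol(xb)
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  diff <- ma - mb
  degenerate <- va == 0 & vb == 0

  if (variant == "pooled" || variant == "moderated") {
    d <- na + nb - 2
    s2 <- ((na - 1) * va + (nb - 1) * vb) / d
    if (variant == "moderated") {
      prior <- moderation_prior(s2[!degenerate], d)
      if (is.finite(prior$d0)) {
        s2 <- (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
      } else {
        s2 <- rep(prior$s02, length(s2))
      }
      df <- d + prior$d0
    } else {
      df <- d
    }
    t <- diff / sqrt(s2 * (1 / na + 1 / nb))
  } else {
    se2a <- va / na
    se2b <- vb / nb
    t <- diff / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  }
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  t[degenerate & diff == 0] <- 0
  p[degenerate & diff == 0] <- 1
  t[degenerate & diff != 0] <- Inf * sign(diff[degenerate & diff != 0])
  p[degenerate & diff != 0] <- 0
  out <- data.frame(t = t, p = p, df = df, degenerate = degenerate,
                    row.names = rownames(mat))
  out
}

# Moment-match the across-feature pooled variances to s^2/s0^2 ~ F(d, d0):
# E = d0/(d0-2), CV^2 = 2(d + d0 - 2)/(d (d0 - 4)). CV^2 d <= 2 has no
# finite solution -> d0 = Inf (all features share one variance).
moderation_prior <- function(s2, d) {
  m1 <- mean(s2)
  cv2 <- stats::var(s2) / m1^2
  if (!is.finite(cv2) || cv2 * d <= 2) {
    return(list(d0 = Inf, s02 = m1))
  }
  d0 <- (2 * d - 4 + 4 * cv2 * d) / (cv2 * d - 2)
  list(d0 = d0, s02 = m1 * (d0 - 2) / d0)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q(i) = min_{j >= i} m * p(j) / j` over the ascending sort, capped at 1
#' and mapped back to input order. Missing entries are excluded from `m` and
#' returned missing.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_schema("p-values outside [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out[ok] <- q
  out
}

#' Per-feature differential table for one level
#'
#' Runs the three-group one-way ANOVA plus one two-group test and fold change
#' per listed comparison, with BH FDR computed within each test family
#' (degenerate features excluded from each family with a logged count).
#'
#' @param mat log2 gene-level matrix, or splicing-index matrix for the exon
#'   level (fold changes are then `2 ^ (difference of group-mean SI)`).
#' @param design sample design.
#' @param comparisons list of `c(group_a, group_b)` pairs; numerator first.
#' @param level `"gene"` or `"exon"` (annotation of the output).
#' @param variant t-test variant, see [two_group_test()].
#' @return `data.frame` of class `differential_table`: `feature_id`, `level`,
#'   `anova_F`, `anova_p`, `anova_fdr`, then `fc_*`, `t_*`, `p_*`, `fdr_*`
#'   per comparison named `<a>_vs_<b>`.
#' @export
build_differential_table <- function(mat, design,
                                     comparisons = list(c("HLHS_RV", "Control_RV"),
                                                        c("HLHS_RV", "Control_LV")),
                                     level = c("gene", "exon"),
                                     variant = "pooled") {
  level <- match.arg(level)
  an <- row_oneway_anova(mat, design)
  if (any(an$degenerate)) {
    es_log(sum(an$degenerate), " degenerate feature(s) excluded from the ",
           level, "-level ANOVA FDR family")
  }
  p_for_fdr <- ifelse(an$degenerate, NA_real_, an$p)
  out <- data.frame(feature_id = rownames(mat), level = level,
                    anova_F = an$F, anova_p = an$p,
                    anova_fdr = bh_fdr(p_for_fdr),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (cmp in comparisons) {
    nm <- paste0(cmp[1L], "_vs_", cmp[2L])
    tt <- two_group_test(mat, design, cmp[1L], cmp[2L], variant = variant)
    out[[paste0("fc_", nm)]] <- fold_change(mat, design, cmp[1L], cmp[2L])
    out[[paste0("t_", nm)]] <- tt$t
    out[[paste0("p_", nm)]] <- tt$p
    out[[paste0("fdr_", nm)]] <- bh_fdr(ifelse(tt$degenerate, NA_real_, tt$p))
  }
  class(out) <- c("differential_table", "data.frame")
  attr(out, "comparisons") <- vapply(comparisons, function(cmp)
    paste0(cmp[1L], "_vs_", cmp[2L]), character(1))
  out
}

#' Compound selection thresholds
#'
#' The gate every downstream set passes through: ANOVA FDR below
#' `anova_fdr_max`, pairwise-test FDR below `pair_fdr_max`, and an absolute
#' fold change above `min_fold` (applied symmetrically, so a 0.6-fold gene —
#' 1/0.6 > 1.5 — qualifies). Clustering displays use the stricter
#' `clustering_min_fold_gene` / `clustering_min_fold_si` folds instead of
#' `min_fold`.
#'
#' @param anova_fdr_max,pair_fdr_max FDR ceilings (default 0.05).
#' @param min_fold minimum symmetric fold change (default 1.5).
#' @param clustering_min_fold_gene,clustering_min_fold_si fold thresholds for
#'   clustering display at gene (default 2) and splicing-index (default 5)
#'   level.
#' @return validated list of class `selection_criteria`.
#' @export
selection_criteria <- function(anova_fdr_max = 0.05, pair_fdr_max = 0.05,
                               min_fold = 1.5, clustering_min_fold_gene = 2,
                               clustering_min_fold_si = 5) {
  stopifnot(anova_fdr_max > 0, pair_fdr_max > 0, min_fold >= 1,
            clustering_min_fold_gene > 0, clustering_min_fold_si > 0)
  structure(list(anova_fdr_max = anova_fdr_max, pair_fdr_max = pair_fdr_max,
                 min_fold = min_fold,
                 clustering_min_fold_gene = clustering_min_fold_gene,
                 clustering_min_fold_si = clustering_min_fold_si),
            class = "selection_criteria")
}

#' Select significant features for one comparison
#'
#' @param diff_table a [build_differential_table()] result.
#' @param criteria a [selection_criteria()].
#' @param comparison comparison name, e.g. `"HLHS_RV_vs_Control_RV"`.
#' @param min_fold override of the fold threshold (used by the clustering
#'   gate); defaults to `criteria$min_fold`.
#' @return character vector of selected feature ids.
#' @export
select_features <- function(diff_table, criteria, comparison,
                            min_fold = criteria$min_fold) {
  fc <- diff_table[[paste0("fc_", comparison)]]
  fdr <- diff_table[[paste0("fdr_", comparison)]]
  if (is.null(fc) || is.null(fdr)) {
    stop_schema("comparison not present in table: ", comparison)
  }
  keep <- !is.na(diff_table$anova_fdr) & !is.na(fdr) &
    diff_table$anova_fdr < criteria$anova_fdr_max &
    fdr < criteria$pair_fdr_max &
    pmax(fc, 1 / fc) > min_fold
  diff_table$feature_id[keep]
}

#' @rdname select_features
#' @details `select_for_clustering()` applies the same significance gates but
#'   the clustering fold threshold for the table's level (2-fold on gene
#'   intensity, 5-fold on splicing index).
#' @export
select_for_clustering <- function(diff_table, criteria, comparison) {
  fold <- if (identical(diff_table$level[1L], "exon")) {
    criteria$clustering_min_fold_si
  } else {
    criteria$clustering_min_fold_gene
  }
  select_features(diff_table, criteria, comparison, min_fold = fold)
}

#' qPCR relative fold change (delta-delta-Ct)
#'
#' Normalizes each target gene's cycle threshold to the reference gene per
#' sample (`dCt = Ct(gene) - Ct(ref)`), then reports
#' `2 ^ (mean dCt in group_b - mean dCt in group_a)`: higher cycle counts
#' mean less template, so a gene whose dCt is one cycle lower in `group_a`
#' comes out 2-fold up in `group_a`.
#'
#' @param ct gene x sample matrix of cycle thresholds.
#' @param reference_gene row name of the endogenous control (e.g. 18S rRNA).
#' @param design sample design.
#' @param group_a,group_b groups to compare (fold is "a over b").
#' @return named vector of linear fold changes (reference gene excluded).
#' @export
qpcr_fold_change <- function(ct, reference_gene, design, group_a, group_b) {
  if (!reference_gene %in% rownames(ct)) {
    stop_schema("reference gene missing from the Ct table: ", reference_gene)
  }
  ref <- ct[reference_gene, ]
  if (anyNA(ref)) stop_schema("reference gene has missing Ct values")
  dct <- sweep(ct, 2L, ref, `-`)
  cols <- group_columns(design, colnames(ct))
  folds <- 2 ^ (rowMeans(dct[, cols[[group_b]], drop = FALSE]) -
                  rowMeans(dct[, cols[[group_a]], drop = FALSE]))
  folds[setdiff(names(folds), reference_gene)]
}
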