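# Sample-segregation analyses: median centering, centered-correlation
# distance, UPGMA (average-linkage) hierarchical clustering with newick
# export, and PCA of the sample x feature matrix.

#' Median-center each row
#'
#' Subtracts every feature's median so heatmap units read as log2 deviation
#' from that feature's across-sample median; idempotent.
#'
#' @param mat numeric matrix without missing values.
#' @return matrix with all row medians zero.
#' @export
median_center <- function(mat) {
  if (anyNA(mat)) stop_schema("median_center: missing values")
  sweep(mat, 1L, apply(mat, 1L, stats::median), `-`)
}

#' Centered-correlation distance matrix
#'
#' `d(x, y) = 1 - Pearson r(x, y)` between rows (or columns): 0 for
#' perfectly correlated profiles, 2 for perfectly anti-correlated ones.
#'
#' @param mat numeric matrix.
#' @param axis distance between `"rows"` (features) or `"columns"` (samples).
#' @return symmetric distance matrix with zero diagonal.
#' @export
centered_correlation_distance <- function(mat, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  x <- if (axis == "rows") t(mat) else mat
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    stop_schema("zero-variance vector(s): ",
                paste(utils::head(colnames(x)[v == 0], 5L), collapse = ", "))
  }
  d <- 1 - stats::cor(x)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates with the unweighted mean of all cross-pair distances as the
#' inter-cluster distance. Returns the merge history plus the input distance
#' matrix, and serializes to newick with merge heights as node depths.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @return object of class `cluster_tree`: `merge`, `height`, `order`,
#'   `labels`, and the underlying `hclust`.
#' @export
average_linkage <- function(d) {
  dd <- stats::as.dist(d)
  if (attr(dd, "Size") < 2L) stop_schema("clustering needs >= 2 items")
  hc <- stats::hclust(dd, method = "average")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, metric = "centered_correlation",
                 linkage = "average", hclust = hc),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree:", length(x$labels), "leaves,", x$linkage, "linkage;",
      "merge heights", format(min(x$height), digits = 4), "..",
      format(max(x$height), digits = 4), "\n")
  invisible(x)
}

#' @rdname average_linkage
#' @param tree a `cluster_tree`.
#' @details `as_newick()` uses branch lengths derived from merge heights
#'   (each child branch spans the height difference to its parent merge).
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  ape::write.tree(ape::as.phylo(tree$hclust))
}

#' @rdname average_linkage
#' @param k number of branches to cut the tree into.
#' @export
cut_tree <- function(tree, k) {
  stats::cutree(tree$hclust, k = k)
}

#' Principal component analysis of samples
#'
#' Centers each feature across samples and decomposes by SVD; the explained
#' variance fraction of component `k` is its squared singular value over the
#' total.
#'
#' @param mat feature x sample matrix (samples become the observations).
#' @param n_components components to keep; truncated to the matrix rank with
#'   a warning when larger.
#' @return object of class `pca_result`: `scores` (samples x k), `loadings`
#'   (features x k), `explained` (descending fractions, summing to <= 1).
#' @export
pca <- function(mat, n_components = 2L) {
  if (ncol(mat) < 2L) stop_schema("PCA needs >= 2 samples")
  x <- t(mat)
  x <- sweep(x, 2L, colMeans(x), `-`)
  pr <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  rank <- sum(pr$sdev > pr$sdev[1L] * 1e-10)
  if (n_components > rank) {
    warning("n_components reduced to the matrix rank (", rank, ")", call. = FALSE)
    n_components <- rank
  }
  keep <- seq_len(n_components)
  structure(list(scores = pr$x[, keep, drop = FALSE],
                 loadings = pr$rotation[, keep, drop = FALSE],
                 explained = (pr$sdev^2 / sum(pr$sdev^2))[keep]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples x", ncol(x$scores),
      "components; explained:",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}
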