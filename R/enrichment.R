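# Over-representation analysis: for each gene set, the one-sided
# hypergeometric tail probability that a selection of n genes from the
# N-gene detectable universe contains at least the observed k members of the
# set (K of whose members are in the universe), BH-adjusted across sets.

#' Hypergeometric over-representation analysis
#'
#' The universe should be the detectable genes (the reference set for
#' pathway statistics), not the whole genome. Selected ids outside the
#' universe are dropped with a warning; set members are intersected with the
#' universe; sets retaining fewer than `min_set_size` members are skipped.
#'
#' @param selected_ids selected gene (transcript-cluster) ids.
#' @param universe_ids the detectable-gene universe.
#' @param gene_sets a `gene_set_collection` from [read_gmt()], or a named
#'   list of character vectors.
#' @param min_set_size minimum in-universe set size to test (default 3).
#' @return `data.frame` of class `enrichment_result` with columns `set`,
#'   `k`, `K`, `n`, `N`, `p`, `fdr`, in input set order.
#' @export
hypergeometric_ora <- function(selected_ids, universe_ids, gene_sets,
                               min_set_size = 3L) {
  universe <- unique(as.character(universe_ids))
  selected <- unique(as.character(selected_ids))
  if (length(universe) == 0L) stop_schema("empty universe")
  if (length(selected) == 0L) stop_schema("empty selection")
  if (length(gene_sets) == 0L) stop_schema("empty gene-set collection")
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    warning(length(outside), " selected id(s) outside the universe dropped",
            call. = FALSE)
    selected <- intersect(selected, universe)
    if (length(selected) == 0L) stop_schema("no selected ids inside the universe")
  }
  members <- lapply(gene_sets, function(s) {
    m <- if (is.list(s)) s$members else s
    intersect(unique(as.character(m)), universe)
  })
  K <- lengths(members)
  keep <- K >= min_set_size
  if (any(!keep)) {
    es_log(sum(!keep), " gene set(s) with < ", min_set_size,
           " in-universe members skipped")
  }
  N <- length(universe)
  n <- length(selected)
  k <- vapply(members[keep], function(m) length(intersect(m, selected)), integer(1))
  # P[X >= k] for X ~ Hypergeometric(N, K, n); phyper counts white draws
  p <- stats::phyper(k - 1L, K[keep], N - K[keep], n, lower.tail = FALSE)
  out <- data.frame(set = names(members)[keep], k = k, K = K[keep],
                    n = n, N = N, p = p, fdr = bh_fdr(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("enrichment_result", "data.frame")
  out
}
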