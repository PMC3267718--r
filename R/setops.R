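# Venn arithmetic over selected-feature id sets and the spliced-versus-
# differentially-expressed overlap summaries.

#' Two-set Venn partition counts
#'
#' @param set_a,set_b character vectors of feature ids (deduplicated).
#' @param labels length-2 character vector naming the sets.
#' @return list of class `venn_summary`: `only_a`, `only_b`, `both`,
#'   `union`, `labels`.
#' @export
venn2 <- function(set_a, set_b, labels = c("A", "B")) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  both <- length(intersect(a, b))
  out <- list(only_a = length(a) - both, only_b = length(b) - both,
              both = both, union = length(union(a, b)), labels = labels)
  stopifnot(out$union == out$only_a + out$only_b + out$both)
  structure(out, class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("venn: %s only %d | both %d | %s only %d  (union %d)\n",
              x$labels[1L], x$only_a, x$both, x$labels[2L], x$only_b, x$union))
  invisible(x)
}

#' Three-set Venn region counts
#'
#' Counts only (no geometry): the seven regions of three id sets.
#'
#' @param set_a,set_b,set_c character vectors of feature ids.
#' @return named integer vector of the 7 region counts
#'   (`a`, `b`, `c`, `ab`, `ac`, `bc`, `abc`).
#' @export
venn3 <- function(set_a, set_b, set_c) {
  a <- unique(as.character(set_a)); b <- unique(as.character(set_b))
  cc <- unique(as.character(set_c))
  abc <- length(Reduce(intersect, list(a, b, cc)))
  ab <- length(intersect(a, b)) - abc
  ac <- length(intersect(a, cc)) - abc
  bc <- length(intersect(b, cc)) - abc
  c(a = length(a) - ab - ac - abc, b = length(b) - ab - bc - abc,
    c = length(cc) - ac - bc - abc, ab = ab, ac = ac, bc = bc, abc = abc)
}

#' Spliced-versus-expressed overlap summary
#'
#' How many of the alternatively spliced genes also show significant
#' gene-level expression changes, and what integer percentage of the spliced
#' set that is (rounded to the nearest integer, ties away from zero).
#'
#' @param spliced_ids ids of genes called alternatively spliced.
#' @param de_ids ids of genes called differentially expressed.
#' @return list of class `overlap_summary`: `count_both`, `n_spliced`,
#'   `percent` (NA with a warning when the spliced set is empty).
#' @export
overlap_summary <- function(spliced_ids, de_ids) {
  s <- unique(as.character(spliced_ids))
  d <- unique(as.character(de_ids))
  both <- length(intersect(s, d))
  if (length(s) == 0L) {
    warning("empty spliced set: overlap percentage undefined", call. = FALSE)
    pct <- NA_real_
  } else {
    pct <- floor(100 * both / length(s) + 0.5)  # ties away from zero
  }
  structure(list(count_both = both, n_spliced = length(s), percent = pct),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap: %d of %d spliced genes also differentially expressed (%s%%)\n",
              x$count_both, x$n_spliced,
              if (is.na(x$percent)) "NA" else format(x$percent)))
  invisible(x)
}

#' Collapse exon-level selections to transcript clusters
#'
#' Spliced-versus-expressed comparisons are made at gene granularity: exon
#' probe-set ids are mapped to their owning clusters and deduplicated.
#'
#' @param probeset_ids exon probe-set ids.
#' @param annotation probe-set annotation.
#' @return character vector of unique transcript-cluster ids.
#' @export
collapse_to_clusters <- function(probeset_ids, annotation) {
  hit <- match(probeset_ids, annotation$probeset_id)
  if (anyNA(hit)) {
    stop_schema("probe sets absent from annotation: ",
                paste(utils::head(probeset_ids[is.na(hit)], 5L), collapse = ", "))
  }
  unique(annotation$transcript_cluster_id[hit])
}
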