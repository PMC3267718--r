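# Readers/writers for the plain-text formats the pipeline exchanges:
# probe-set annotation (CSV), intensity matrices (TSV), sample designs (TSV)
# and gene sets (GMT). Row order from the input file is preserved everywhere;
# filters drop rows but never reorder the survivors.

ANNOTATION_COLUMNS <- c("probeset_id", "transcript_cluster_id", "n_probes",
                        "level", "cross_hyb", "exon_index", "gc_fraction")

#' Read a probe-set annotation table
#'
#' The annotation maps exon-level probe sets to their transcript clusters
#' (the array's gene-level unit) and carries the QC fields the detection and
#' filtering stages need: the annotation confidence tier (`core`, `extended`,
#' `full`), a cross-hybridization flag, the ordinal exon position within the
#' cluster, and the mean probe GC fraction used for GC-matched background
#' binning. Comment lines starting with `#` (as in vendor annotation CSVs)
#' are skipped.
#'
#' @param path CSV file with a header row and at least the columns
#'   `probeset_id`, `transcript_cluster_id`, `n_probes`, `level`, `cross_hyb`,
#'   `exon_index`, `gc_fraction`.
#' @param level_filter optional character vector of tiers to retain,
#'   e.g. `"core"` to restrict analysis to the high-confidence probe sets.
#' @param drop_cross_hyb drop probe sets flagged as cross-hybridizing
#'   (default `TRUE`).
#' @return a `data.frame` with the columns above, input row order preserved.
#' @export
read_annotation <- function(path, level_filter = NULL, drop_cross_hyb = TRUE) {
  ann <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing)) {
    stop_schema("annotation file missing required column(s): ",
                paste(missing, collapse = ", "))
  }
  ann <- ann[, ANNOTATION_COLUMNS]
  ann$probeset_id <- as.character(ann$probeset_id)
  ann$transcript_cluster_id <- as.character(ann$transcript_cluster_id)
  ann$cross_hyb <- as.logical(ann$cross_hyb)
  if (anyDuplicated(ann$probeset_id)) {
    stop_schema("duplicate probeset_id in annotation: ",
                paste(unique(ann$probeset_id[duplicated(ann$probeset_id)]), collapse = ", "))
  }
  validate_annotation(ann)
  n0 <- nrow(ann)
  if (!is.null(level_filter)) {
    ann <- ann[ann$level %in% level_filter, , drop = FALSE]
    es_log("level filter (", paste(level_filter, collapse = "/"), "): dropped ",
           n0 - nrow(ann), " of ", n0, " probe sets")
  }
  n1 <- nrow(ann)
  if (isTRUE(drop_cross_hyb)) {
    ann <- ann[!ann$cross_hyb, , drop = FALSE]
    es_log("cross-hybridization filter: dropped ", n1 - nrow(ann), " of ", n1,
           " probe sets")
  }
  rownames(ann) <- NULL
  ann
}

validate_annotation <- function(ann) {
  if (any(ann$n_probes < 1)) stop_schema("annotation: n_probes must be >= 1")
  if (any(ann$gc_fraction < 0 | ann$gc_fraction > 1)) {
    stop_schema("annotation: gc_fraction outside [0, 1]")
  }
  if (any(ann$exon_index < 0)) stop_schema("annotation: exon_index must be >= 0")
  dup <- vapply(split(ann$exon_index, ann$transcript_cluster_id),
                anyDuplicated, integer(1))
  if (any(dup > 0)) {
    stop_schema("annotation: duplicated exon_index within cluster(s): ",
                paste(names(dup)[dup > 0], collapse = ", "))
  }
  invisible(ann)
}

#' @rdname read_annotation
#' @param ann annotation `data.frame` as returned by [read_annotation()].
#' @export
write_annotation <- function(ann, path) {
  utils::write.csv(ann[, ANNOTATION_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an intensity matrix
#'
#' Matrices are TSV (or CSV, by file extension) with the feature identifiers
#' in a first column named `feature_id` and one column per sample. The caller
#' declares the feature level (`probe`, `exon_probeset`, `transcript_cluster`)
#' and the scale; linear-scale values must be strictly positive, log2-scale
#' values may be negative.
#'
#' @param path TSV/CSV file.
#' @param level feature level tag.
#' @param scale `"linear"` or `"log2"`.
#' @return numeric matrix (features x samples) with attributes `level` and
#'   `scale`.
#' @export
read_matrix <- function(path,
                        level = c("probe", "exon_probeset", "transcript_cluster"),
                        scale = c("linear", "log2")) {
  level <- match.arg(level)
  scale <- match.arg(scale)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "")
  if (ncol(raw) < 2L) stop_schema("matrix file needs a feature_id column plus >= 1 sample")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) stop_schema("duplicate feature ids in ", path)
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_schema(sprintf("non-numeric cell '%s' at row %d, column '%s' in %s",
                        cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                        colnames(cells)[bad[1L, 2L]], path))
  }
  dimnames(vals) <- list(ids, colnames(cells))
  if (scale == "linear" && any(vals <= 0)) {
    bad <- which(vals <= 0, arr.ind = TRUE)
    stop_schema(sprintf("non-positive value on linear scale at row %d ('%s'), column '%s'",
                        bad[1L, 1L], ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  structure(vals, level = level, scale = scale)
}

#' @rdname read_matrix
#' @param mat numeric matrix with feature row names and sample column names.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write sample design tables
#'
#' A design is a two-column TSV (`sample_id`, `group`) assigning every array
#' to a treatment group, e.g. the three-group design HLHS-RV / Control-RV /
#' Control-LV.
#'
#' @param path TSV file.
#' @return `data.frame` with character columns `sample_id` and `group`.
#' @export
read_design <- function(path) {
  design <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, colClasses = "character")
  check_design(design)
}

#' @rdname read_design
#' @param design design `data.frame`.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[, c("sample_id", "group")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated member ids
#' (transcript-cluster ids in this pipeline). Duplicate members within a set
#' are removed with a warning; a line with fewer than three fields is a
#' format error.
#'
#' @param path GMT file.
#' @return named list of class `gene_set_collection`; each element has
#'   `description` and `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_schema("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT set '", fields[1L], "' lists duplicate members; deduplicated",
              call. = FALSE)
      members <- unique(members)
    }
    sets[[fields[1L]]] <- list(description = fields[2L], members = members)
  }
  structure(sets, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param sets a `gene_set_collection`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x), "set(s)\n")
  for (nm in utils::head(names(x), 10L)) {
    cat("  ", nm, ": ", length(x[[nm]]$members), " members\n", sep = "")
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}
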