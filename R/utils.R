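#' @keywords internal
"_PACKAGE"

# Stage-by-stage progress/count messages go through one switchable channel so
# pipeline logs stay greppable and tests can silence them.
es_log <- function(..., verbose = getOption("exonsplice.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[exonsplice] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_schema <- function(...) stop(..., call. = FALSE)

#' Map probe identifiers to their probe-set identifiers
#'
#' Probe-level feature ids follow the convention `<probeset_id>:<probe index>`;
#' everything up to the final colon names the owning probe set.
#'
#' @param probe_ids character vector of probe-level feature ids.
#' @return character vector of probe-set ids, same length.
#' @export
#' @examples
#' probe_probeset(c("TC0001_PS01:1", "TC0001_PS01:2", "TC0002_PS03:4"))
probe_probeset <- function(probe_ids) {
  out <- sub(":[^:]*$", "", probe_ids)
  bad <- out == probe_ids
  if (any(bad)) {
    stop_schema("probe ids without a ':<index>' suffix: ",
                paste(utils::head(probe_ids[bad], 5L), collapse = ", "))
  }
  out
}

# Shared validation: a design data.frame with sample_id and group columns,
# groups as a factor in first-appearance order.
check_design <- function(design, sample_ids = NULL, min_per_group = 1L) {
  if (!is.data.frame(design) || !all(c("sample_id", "group") %in% names(design))) {
    stop_schema("design must be a data.frame with columns 'sample_id' and 'group'")
  }
  if (anyDuplicated(design$sample_id)) {
    stop_schema("duplicate sample_id in design: ",
                paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ", "))
  }
  design$group <- as.character(design$group)
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, design$sample_id)
    if (length(missing)) {
      stop_schema("samples absent from design: ", paste(missing, collapse = ", "))
    }
    design <- design[match(sample_ids, design$sample_id), , drop = FALSE]
  }
  tab <- table(design$group)
  if (any(tab < min_per_group)) {
    stop_schema("groups with fewer than ", min_per_group, " samples: ",
                paste(names(tab)[tab < min_per_group], collapse = ", "))
  }
  design
}

group_columns <- function(design, sample_ids) {
  design <- check_design(design, sample_ids = sample_ids)
  split(seq_along(sample_ids), factor(design$group, levels = unique(design$group)))
}
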