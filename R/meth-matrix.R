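#' Probe-by-sample methylation matrix
#'
#' Lightweight container for an array methylation matrix: a numeric grid with
#' unique probe rownames and sample colnames, tagged with the value space the
#' numbers live in. Beta values are methylation proportions in `[0, 1]`;
#' M-values are their logit2 transform and may be any finite real.
#'
#' @param values Numeric matrix, probes in rows, samples in columns, with
#'   unique non-empty dimnames. Missing values are rejected.
#' @param value_space Either `"beta"` or `"M"`.
#'
#' @return An object of class `meth_matrix`: a list with elements `values`
#'   and `value_space`.
#' @export
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.2, 0.8), nrow = 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' meth_matrix(m, "beta")
meth_matrix <- function(values, value_space = c("beta", "M")) {
  value_space <- match.arg(value_space)
  if (!is.matrix(values) || !is.numeric(values)) {
    mp_abort("`values` must be a numeric matrix", "mp_validation_error")
  }
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid) || any(!nzchar(pid)) || any(!nzchar(sid))) {
    mp_abort("`values` must have non-empty probe rownames and sample colnames",
             "mp_validation_error")
  }
  if (anyDuplicated(pid)) {
    mp_abort(sprintf("duplicated probe id: %s", pid[duplicated(pid)][1L]),
             "mp_format_error")
  }
  if (anyDuplicated(sid)) {
    mp_abort(sprintf("duplicated sample id: %s", sid[duplicated(sid)][1L]),
             "mp_format_error")
  }
  if (anyNA(values)) {
    mp_abort("missing values are not supported in methylation matrices",
             "mp_validation_error")
  }
  if (value_space == "beta" && (any(values < 0) || any(values > 1))) {
    mp_abort("beta-space values must lie in [0, 1]", "mp_validation_error")
  }
  if (value_space == "M" && any(!is.finite(values))) {
    mp_abort("M-space values must be finite", "mp_validation_error")
  }
  structure(list(values = values, value_space = value_space),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("<meth_matrix> %d probes x %d samples (%s-space)\n",
              nrow(x$values), ncol(x$values), x$value_space))
  invisible(x)
}

#' Probe and sample identifiers of a methylation matrix
#'
#' @param x A `meth_matrix`.
#' @return Character vector of identifiers.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Construct and validate a sample sheet
#'
#' A sample sheet records, for each array column, the sample identifier, the
#' tissue class (`"tumor"` or `"normal"`), and a batch label (typically the
#' cohort of origin).
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Character vector, each element `"tumor"` or `"normal"`.
#' @param batch Character vector of batch labels (recycled if length 1).
#'
#' @return A validated `data.frame` with columns `sample_id`, `group`, `batch`.
#' @export
sample_sheet <- function(sample_id, group, batch = "batch1") {
  df <- data.frame(sample_id = as.character(sample_id),
                   group = as.character(group),
                   batch = rep_len(as.character(batch), length(sample_id)),
                   stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname sample_sheet
#' @param sheet A data frame to validate.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "group", "batch")
  if (!is.data.frame(sheet) || !all(need %in% names(sheet))) {
    mp_abort("sample sheet must have columns sample_id, group, batch",
             "mp_validation_error")
  }
  if (anyDuplicated(sheet$sample_id)) {
    mp_abort(sprintf("duplicated sample id in sheet: %s",
                     sheet$sample_id[duplicated(sheet$sample_id)][1L]),
             "mp_validation_error")
  }
  bad <- setdiff(unique(sheet$group), c("tumor", "normal"))
  if (length(bad)) {
    mp_abort(sprintf("group labels must be 'tumor' or 'normal', found: %s",
                     paste(bad, collapse = ", ")),
             "mp_validation_error")
  }
  if (anyNA(sheet$batch) || any(!nzchar(sheet$batch))) {
    mp_abort("every sample needs a non-empty batch label", "mp_validation_error")
  }
  sheet[need]
}

# Align a sheet's rows to a matrix's columns; errors if any sample is missing.
align_sheet <- function(matrix, sheet) {
  sheet <- validate_sample_sheet(sheet)
  idx <- match(sample_ids(matrix), sheet$sample_id)
  if (anyNA(idx)) {
    mp_abort(sprintf("sample sheet is missing sample(s): %s",
                     paste(sample_ids(matrix)[is.na(idx)], collapse = ", ")),
             "mp_validation_error")
  }
  sheet[idx, , drop = FALSE]
}

# Standard class factor used by all classifiers: "normal" < "tumor",
# "tumor" is the positive class in confusion reports.
as_group_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), c("tumor", "normal"))
  if (length(bad)) {
    mp_abort(sprintf("class labels must be 'tumor'/'normal', found: %s",
                     paste(bad, collapse = ", ")),
             "mp_validation_error")
  }
  factor(x, levels = c("normal", "tumor"))
}
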