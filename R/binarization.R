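#' Exact one-dimensional two-means split
#'
#' Solves 2-means clustering of a numeric vector exactly: over the sorted
#' values, every split between two distinct adjacent values is scored by total
#' within-cluster sum of squares and the global minimum is taken (in one
#' dimension the optimal 2-means clustering is always such a contiguous
#' split, so this is the global optimum Lloyd iterations only approximate,
#' with no seed sensitivity). Ties are broken toward the larger low cluster.
#' Samples in the higher-mean cluster are coded 1, the threshold is the
#' midpoint between the largest low-cluster value and the smallest
#' high-cluster value, and a sample's label is 1 exactly when its value
#' exceeds the threshold.
#'
#' @param values Numeric vector with at least 2 elements, not all identical.
#' @return List with `threshold`, `low_mean`, `high_mean` and integer
#'   `labels` (0/1, parallel to `values`).
#' @export
two_means_split <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    mp_abort("`values` must be >= 2 numbers without missing values",
             "mp_validation_error")
  }
  s <- sort(values)
  n <- length(s)
  if (s[1] == s[n]) {
    mp_abort("all values identical: probe is degenerate for two-means",
             "mp_degenerate_error")
  }
  cs <- cumsum(s)
  css <- cumsum(s^2)
  i <- seq_len(n - 1L)
  wcss <- (css[i] - cs[i]^2 / i) +
    ((css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i))
  wcss[s[i] == s[i + 1L]] <- Inf      # only split between distinct values
  # ties (common for discretised values) resolve to the larger low cluster;
  # the tolerance absorbs float noise of the cumulative-sum evaluation
  tol <- 1e-8 * max(1, css[n] - cs[n]^2 / n)
  best <- max(which(wcss <= min(wcss) + tol))
  threshold <- (s[best] + s[best + 1L]) / 2
  list(threshold = threshold,
       low_mean = cs[best] / best,
       high_mean = (cs[n] - cs[best]) / (n - best),
       labels = as.integer(values > threshold))
}

#' Binarize probes of a methylation matrix
#'
#' Applies [two_means_split()] probe-wise and assembles a sample-by-probe 0/1
#' feature matrix. Degenerate probes (all values identical) are dropped with a
#' warning and listed in the result.
#'
#' @param matrix A [meth_matrix()] (any value space; the split is recomputed
#'   from the values as given).
#' @param probes Probe ids to binarize; default all.
#' @return A `binary_features` object: list with `values` (samples x probes
#'   integer matrix), `splits` (data frame `probe_id`, `threshold`,
#'   `low_mean`, `high_mean`) and `dropped` (character).
#' @export
binarize_matrix <- function(matrix, probes = NULL) {
  if (!inherits(matrix, "meth_matrix")) {
    mp_abort("`matrix` must be a meth_matrix", "mp_validation_error")
  }
  if (is.null(probes)) probes <- probe_ids(matrix)
  missing_probes <- setdiff(probes, probe_ids(matrix))
  if (length(missing_probes)) {
    mp_abort(sprintf("probe(s) not in matrix: %s",
                     paste(missing_probes, collapse = ", ")),
             "mp_validation_error")
  }
  n_samples <- length(sample_ids(matrix))
  keep <- character(0)
  dropped <- character(0)
  cols <- list()
  splits <- list()
  for (p in probes) {
    res <- tryCatch(two_means_split(matrix$values[p, ]),
                    mp_degenerate_error = function(e) NULL)
    if (is.null(res)) {
      dropped <- c(dropped, p)
      next
    }
    keep <- c(keep, p)
    cols[[p]] <- res$labels
    splits[[p]] <- data.frame(probe_id = p, threshold = res$threshold,
                              low_mean = res$low_mean, high_mean = res$high_mean,
                              stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    mp_warn(sprintf("dropped %d degenerate probe(s): %s", length(dropped),
                    paste(dropped, collapse = ", ")),
            "mp_degenerate_warning")
  }
  if (!length(keep)) {
    mp_abort("no probe survived binarization", "mp_validation_error")
  }
  values <- matrix(unlist(cols, use.names = FALSE), nrow = n_samples,
                   dimnames = list(sample_ids(matrix), keep))
  structure(list(values = values,
                 splits = do.call(rbind, c(splits, list(make.row.names = FALSE))),
                 dropped = dropped),
            class = "binary_features")
}

#' @export
print.binary_features <- function(x, ...) {
  cat(sprintf("<binary_features> %d samples x %d probes (%d dropped)\n",
              nrow(x$values), ncol(x$values), length(x$dropped)))
  invisible(x)
}

# Accept either a binary_features object or a plain 0/1 matrix.
feature_values <- function(x) {
  if (inherits(x, "binary_features")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  mp_abort("expected a binary_features object or a numeric matrix",
           "mp_validation_error")
}

#' Re-binarize a marker panel on a new cohort
#'
#' Recomputes the two-means splits of the panel probes from the new cohort's
#' own values — training thresholds are deliberately not reused, so the
#' binary coding is robust to between-platform and between-cohort shifts.
#'
#' @param new_matrix A [meth_matrix()] for the new cohort.
#' @param panel_probes Character vector of panel probe ids.
#' @return A `binary_features` object over exactly `panel_probes`.
#' @export
rebinarize_panel <- function(new_matrix, panel_probes) {
  missing_probes <- setdiff(panel_probes, probe_ids(new_matrix))
  if (length(missing_probes)) {
    mp_abort(sprintf("panel probe(s) missing from cohort: %s",
                     paste(missing_probes, collapse = ", ")),
             "mp_validation_error")
  }
  out <- binarize_matrix(new_matrix, panel_probes)
  if (length(out$dropped)) {
    mp_abort(sprintf("panel probe(s) degenerate in new cohort: %s",
                     paste(out$dropped, collapse = ", ")),
             "mp_validation_error")
  }
  out
}
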