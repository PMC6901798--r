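#' Beta/M value-space transforms
#'
#' `beta_to_m()` maps beta values to M-values `log2(b / (1 - b))` after
#' clipping betas into `[epsilon, 1 - epsilon]` so boundary values stay
#' finite; `m_to_beta()` is the inverse `2^M / (1 + 2^M)`. The round trip is
#' the identity for betas inside the clip range. Differential analysis runs in
#' M space, where array effects are additive and group differences of the size
#' reported for tumor/normal CpGs are representable.
#'
#' @param matrix A [meth_matrix()] in the appropriate space.
#' @param epsilon Clip bound in (0, 0.5); default 1e-6.
#' @return A [meth_matrix()] in the other value space.
#' @export
beta_to_m <- function(matrix, epsilon = 1e-6) {
  if (!inherits(matrix, "meth_matrix")) {
    mp_abort("`matrix` must be a meth_matrix", "mp_validation_error")
  }
  if (matrix$value_space != "beta") {
    mp_abort("beta_to_m() requires a beta-space matrix", "mp_state_error")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 ||
      epsilon >= 0.5) {
    mp_abort("`epsilon` must lie in (0, 0.5)", "mp_config_error")
  }
  b <- pmin(pmax(matrix$values, epsilon), 1 - epsilon)
  meth_matrix(log2(b / (1 - b)), "M")
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(matrix) {
  if (!inherits(matrix, "meth_matrix")) {
    mp_abort("`matrix` must be a meth_matrix", "mp_validation_error")
  }
  if (matrix$value_space != "M") {
    mp_abort("m_to_beta() requires an M-space matrix", "mp_state_error")
  }
  meth_matrix(2^matrix$values / (1 + 2^matrix$values), "beta")
}

#' Gene-wise one-way batch adjustment
#'
#' Removes additive batch effects probe by probe: each value is shifted by
#' minus its probe's batch mean plus the probe's grand mean, i.e. the fitted
#' batch effect of a per-probe one-way ANOVA on batch is subtracted. Each
#' probe's grand mean is preserved exactly, and after adjustment every batch
#' mean equals the grand mean, so the operation is idempotent. No variance
#' scaling is performed. Intended to run on M-values, where the additive model
#' is defensible on an unbounded scale.
#'
#' @param matrix A [meth_matrix()].
#' @param sheet Sample sheet supplying the batch label of every sample.
#' @return List with the adjusted `matrix` and a `report` data frame with one
#'   row per (probe, batch): means before/after and the probe grand mean.
#' @export
batch_adjust <- function(matrix, sheet) {
  if (!inherits(matrix, "meth_matrix")) {
    mp_abort("`matrix` must be a meth_matrix", "mp_validation_error")
  }
  sheet <- align_sheet(matrix, sheet)
  batches <- sheet$batch
  x <- matrix$values
  grand <- rowMeans(x)
  levels <- unique(batches)
  before <- after <- matrix(NA_real_, nrow(x), length(levels),
                            dimnames = list(rownames(x), levels))
  for (b in levels) {
    idx <- batches == b
    if (!any(idx)) {
      mp_abort(sprintf("batch '%s' has no samples", b), "mp_validation_error")
    }
    bm <- rowMeans(x[, idx, drop = FALSE])
    before[, b] <- bm
    x[, idx] <- x[, idx, drop = FALSE] - bm + grand
    after[, b] <- rowMeans(x[, idx, drop = FALSE])
  }
  report <- data.frame(
    probe_id = rep(rownames(x), times = length(levels)),
    batch = rep(levels, each = nrow(x)),
    mean_before = as.vector(before),
    mean_after = as.vector(after),
    grand_mean = rep(grand, times = length(levels)),
    stringsAsFactors = FALSE
  )
  list(matrix = meth_matrix(x, matrix$value_space), report = report)
}
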