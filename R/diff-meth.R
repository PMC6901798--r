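#' Per-probe two-group linear fits
#'
#' For every probe, computes the tumor-minus-normal difference of M-value
#' group means (`logFC`), the pooled within-group residual variance `s2_g`
#' on `d_g = n_tumor + n_normal - 2` degrees of freedom, and the variance
#' unscaling factor `v_g = 1/n_tumor + 1/n_normal`, i.e. the per-probe
#' sufficient statistics of the two-group linear model.
#'
#' @param matrix An M-space [meth_matrix()] (batch-adjusted upstream).
#' @param sheet Sample sheet with tumor/normal labels.
#' @return Data frame with columns `probe_id`, `logFC`, `s2_g`, `d_g`, `v_g`.
#' @export
fit_probe_models <- function(matrix, sheet) {
  if (!inherits(matrix, "meth_matrix") || matrix$value_space != "M") {
    mp_abort("fit_probe_models() requires an M-space meth_matrix",
             "mp_state_error")
  }
  sheet <- align_sheet(matrix, sheet)
  grp <- as_group_factor(sheet$group)
  n1 <- sum(grp == "tumor")
  n2 <- sum(grp == "normal")
  if (n1 == 0L || n2 == 0L) {
    mp_abort("both tumor and normal groups must be non-empty", "mp_design_error")
  }
  if (n1 + n2 < 3L) {
    mp_abort("need at least 3 samples in total for residual df >= 1",
             "mp_design_error")
  }
  x <- matrix$values
  xt <- x[, grp == "tumor", drop = FALSE]
  xn <- x[, grp == "normal", drop = FALSE]
  mt <- rowMeans(xt)
  mn <- rowMeans(xn)
  ss <- rowSums((xt - mt)^2) + rowSums((xn - mn)^2)
  d_g <- n1 + n2 - 2L
  data.frame(probe_id = rownames(x),
             logFC = mt - mn,
             s2_g = ss / d_g,
             d_g = d_g,
             v_g = 1 / n1 + 1 / n2,
             stringsAsFactors = FALSE)
}

# Inverse of trigamma by Newton iteration on the reciprocal scale
# (trigamma is strictly decreasing and convex on (0, Inf)).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes variance moderation hyperparameters
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_2` of
#' the scaled inverse chi-square prior on per-probe variances by the method
#' of moments on log variances: with `z_g = log(s2_g)` and
#' `e_g = z_g - digamma(d_g/2) + log(d_g/2)`, solve
#' `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` for `d0` (monotone
#' root-finding via the trigamma inverse) and recover
#' `s0_2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the moment
#' estimate of the excess variance is non-positive, `d0` is infinite and
#' `s0_2 = exp(mean(e))`.
#'
#' @param fits Output of [fit_probe_models()] (>= 2 probes with `d_g >= 1`).
#' @return List with `d0` (possibly `Inf`) and `s0_2`.
#' @export
estimate_moderation <- function(fits) {
  s2 <- fits$s2_g
  d <- fits$d_g
  keep <- is.finite(s2) & s2 > 0 & d >= 1
  if (!any(keep)) {
    mp_abort(paste("all residual variances are zero; variance moderation is",
                   "degenerate — jitter the data or fall back to plain t"),
             "mp_estimation_error")
  }
  if (any(!keep)) {
    mp_warn(sprintf("%d probe(s) with zero residual variance excluded from moderation",
                    sum(!keep)), "mp_degenerate_warning")
  }
  s2 <- s2[keep]
  d <- d[keep]
  m <- length(s2)
  if (m < 2L) {
    mp_abort("need at least 2 probes with positive variance to moderate",
             "mp_estimation_error")
  }
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- sum((e - ebar)^2) / (m - 1) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(ebar)
  }
  list(d0 = d0, s0_2 = s0_2)
}

# Posterior (shrunken) variances: convex combination of prior and observed.
posterior_variance <- function(fits, moderation) {
  if (is.infinite(moderation$d0)) {
    rep(moderation$s0_2, nrow(fits))
  } else {
    (moderation$d0 * moderation$s0_2 + fits$d_g * fits$s2_g) /
      (moderation$d0 + fits$d_g)
  }
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each probe's variance toward the prior,
#' `s2_post = (d0 s0_2 + d_g s2_g) / (d0 + d_g)`, forms
#' `t = logFC / sqrt(s2_post * v_g)`, and computes two-sided p-values from a
#' t distribution on `d0 + d_g` degrees of freedom (capped at 1e6; the normal
#' limit when `d0` is infinite).
#'
#' @param fits Output of [fit_probe_models()].
#' @param moderation Output of [estimate_moderation()].
#' @return A DMP table: data frame with columns `probe_id`, `symbol` (NA),
#'   `logFC`, `t`, `p`, `adj_p` (NA until [bh_adjust()]), `direction`.
#' @export
moderated_tests <- function(fits, moderation) {
  if (!is.list(moderation) || is.null(moderation$d0) || is.null(moderation$s0_2) ||
      moderation$s0_2 <= 0 || moderation$d0 <= 0) {
    mp_abort("invalid moderation estimate", "mp_validation_error")
  }
  s2_post <- posterior_variance(fits, moderation)
  t_mod <- fits$logFC / sqrt(s2_post * fits$v_g)
  df_total <- pmin(moderation$d0 + fits$d_g, 1e6)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(probe_id = fits$probe_id,
             symbol = NA_character_,
             logFC = fits$logFC,
             t = t_mod,
             p = p,
             adj_p = NA_real_,
             direction = ifelse(fits$logFC > 0, "hyper", "hypo"),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false discovery rate adjustment: the adjusted value of the
#' i-th smallest p is `min over j >= i of m * p_(j) / j`, capped at 1, with the
#' original order restored.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    mp_abort("p-values must be numbers in [0, 1]", "mp_validation_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Full differential-methylation analysis of one matrix
#'
#' Convenience composition: [fit_probe_models()], [estimate_moderation()],
#' [moderated_tests()], [bh_adjust()], then sorting by adjusted p ascending
#' (ties broken by |logFC| descending, then probe id).
#'
#' @inheritParams fit_probe_models
#' @return A complete, sorted DMP table.
#' @export
dmp_analysis <- function(matrix, sheet) {
  fits <- fit_probe_models(matrix, sheet)
  moderation <- estimate_moderation(fits)
  tab <- moderated_tests(fits, moderation)
  tab$adj_p <- bh_adjust(tab$p)
  sort_dmp_table(tab)
}

#' @rdname dmp_analysis
#' @param table A DMP table to sort.
#' @export
sort_dmp_table <- function(table) {
  ord <- order(table$adj_p, -abs(table$logFC), table$probe_id)
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call differentially methylated probes
#'
#' Keeps records with `|logFC| > logfc_threshold` and
#' `adj_p < adjp_threshold` (both strict), and assigns the direction
#' (`"hyper"` for logFC > 0, `"hypo"` otherwise).
#'
#' @param table A DMP table with adjusted p-values.
#' @param logfc_threshold Absolute M-value difference threshold (default 1).
#' @param adjp_threshold Adjusted p threshold (default 0.05).
#' @return The filtered DMP table.
#' @export
call_dmps <- function(table, logfc_threshold = 1.0, adjp_threshold = 0.05) {
  if (nrow(table) == 0L) return(table)
  if (anyNA(table$adj_p)) {
    mp_abort("adjusted p-values must be present before calling DMPs",
             "mp_validation_error")
  }
  keep <- abs(table$logFC) > logfc_threshold & table$adj_p < adjp_threshold
  out <- table[keep, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Summarise a DMP table
#'
#' Counts hyper/hypomethylated probes and picks out the extreme records.
#'
#' @param table A DMP table.
#' @return A `dmp_summary` list: `n_total`, `n_hyper`, `n_hypo`, and (absent
#'   for an empty table) the rows `max_logfc`, `min_logfc` and `top` (smallest
#'   adjusted p).
#' @export
summarize_dmps <- function(table) {
  out <- list(n_total = nrow(table),
              n_hyper = sum(table$direction == "hyper"),
              n_hypo = sum(table$direction == "hypo"))
  if (nrow(table) > 0L) {
    out$max_logfc <- table[which.max(table$logFC), , drop = FALSE]
    out$min_logfc <- table[which.min(table$logFC), , drop = FALSE]
    out$top <- table[which.min(table$adj_p), , drop = FALSE]
  }
  structure(out, class = "dmp_summary")
}

#' @export
print.dmp_summary <- function(x, ...) {
  cat(sprintf("<dmp_summary> %d probes (%d hyper / %d hypo)\n",
              x$n_total, x$n_hyper, x$n_hypo))
  if (x$n_total > 0L) {
    cat(sprintf("  max logFC %.2f (%s), min logFC %.2f (%s), top adj p %.3g (%s)\n",
                x$max_logfc$logFC, x$max_logfc$probe_id,
                x$min_logfc$logFC, x$min_logfc$probe_id,
                x$top$adj_p, x$top$probe_id))
  }
  invisible(x)
}
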