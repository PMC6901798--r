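#' Stratified train/test split
#'
#' Within each class, `round(test_fraction * n_class)` samples (at least 1,
#' at most `n_class - 1`) are drawn to the test set under the seed; the split
#' is disjoint and exhaustive. Stratification guards against a rare class
#' being starved out of either side under heavy imbalance.
#'
#' @param sample_id Sample identifiers.
#' @param labels Tumor/normal labels parallel to `sample_id`.
#' @param test_fraction Fraction held out, in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
train_test_split <- function(sample_id, labels, test_fraction = 0.2, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    mp_abort("`test_fraction` must lie in (0, 1)", "mp_config_error")
  }
  y <- as_group_factor(labels)
  if (nlevels(droplevels(y)) < 2L) {
    mp_abort("both classes must be present to split", "mp_split_error")
  }
  test <- character(0)
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      ids <- sample_id[y == cl]
      if (length(ids) < 2L) {
        mp_abort(sprintf("class '%s' has fewer than 2 samples", cl),
                 "mp_split_error")
      }
      n_test <- min(max(round(test_fraction * length(ids)), 1L),
                    length(ids) - 1L)
      test <- c(test, sample(ids, n_test))
    }
  })
  list(train = setdiff(sample_id, test), test = test)
}

#' ROSE smoothed-bootstrap kernel bandwidth
#'
#' The per-feature Gaussian kernel bandwidth of the smoothed bootstrap,
#' `h_q = (4 / ((d + 2) n_j))^(1 / (d + 4)) * sigma_jq`, where `d` is the
#' number of features, `n_j` the class sample count and `sigma_jq` the
#' class standard deviation of feature `q`.
#'
#' @param d Number of features (>= 1).
#' @param n_j Class sample count (>= 1).
#' @param sigma Class standard deviation of the feature (>= 0).
#' @return The bandwidth (0 exactly when `sigma` is 0).
#' @export
rose_bandwidth <- function(d, n_j, sigma) {
  if (d < 1 || n_j < 1 || any(sigma < 0)) {
    mp_abort("need d >= 1, n_j >= 1, sigma >= 0", "mp_config_error")
  }
  (4 / ((d + 2) * n_j))^(1 / (d + 4)) * sigma
}

#' Smoothed-bootstrap minority oversampling (ROSE style)
#'
#' Tops up the minority class with synthetic samples until the classes are
#' exactly balanced; all original samples are kept untouched. Each synthetic
#' sample is a uniformly drawn minority sample plus independent Gaussian noise
#' per feature with sd [rose_bandwidth()] computed from the minority class.
#' Because the features here are binary, synthetic values are thresholded at
#' 0.5 back to 0/1 by default so train and test live in the same space
#' (`binary = FALSE` keeps the continuous smoothed values).
#'
#' @param features Samples-by-features matrix (or `binary_features`).
#' @param labels Tumor/normal labels parallel to the rows.
#' @param seed Integer seed.
#' @param binary Threshold synthetic values back to 0/1 (default TRUE).
#' @return List with the rebalanced `features` matrix and `labels` factor.
#' @export
rose_oversample <- function(features, labels, seed = 1L, binary = TRUE) {
  x <- feature_values(features)
  y <- as_group_factor(labels)
  counts <- table(y)
  if (any(counts == 0L)) {
    mp_abort("minority class is empty", "mp_design_error")
  }
  n_syn <- abs(counts[["tumor"]] - counts[["normal"]])
  if (n_syn == 0L) {
    return(list(features = x, labels = y))
  }
  minority <- if (counts[["tumor"]] < counts[["normal"]]) "tumor" else "normal"
  xm <- x[y == minority, , drop = FALSE]
  d <- ncol(x)
  sigma <- apply(xm, 2L, stats::sd)
  if (nrow(xm) == 1L) {
    mp_warn("minority class has a single sample: falling back to exact duplication",
            "mp_degenerate_warning")
    sigma <- rep(0, d)
  }
  sigma[is.na(sigma)] <- 0
  h <- rose_bandwidth(d, nrow(xm), sigma)
  syn <- withr::with_seed(seed, {
    idx <- sample.int(nrow(xm), n_syn, replace = TRUE)
    noise <- matrix(stats::rnorm(n_syn * d), nrow = n_syn) *
      matrix(h, nrow = n_syn, ncol = d, byrow = TRUE)
    xm[idx, , drop = FALSE] + noise
  })
  if (binary) syn <- (syn > 0.5) + 0L
  rownames(syn) <- sprintf("rose_%04d", seq_len(n_syn))
  list(features = rbind(x, syn),
       labels = factor(c(as.character(y), rep(minority, n_syn)),
                       levels = levels(y)))
}

#' Train a random forest / predict class labels
#'
#' Thin seeded wrapper around the ensemble: same seed implies the same fitted
#' forest and hence identical predictions.
#'
#' @param features Samples-by-features matrix (or `binary_features`).
#' @param labels Tumor/normal labels parallel to the rows.
#' @param trees Number of trees.
#' @param seed Integer seed.
#' @return `train_forest` returns a `meth_rf` classifier reference;
#'   `predict_forest` returns a character vector of `"tumor"`/`"normal"`.
#' @export
train_forest <- function(features, labels, trees = 500L, seed = 1L) {
  x <- feature_values(features)
  y <- droplevels(as_group_factor(labels))
  if (nlevels(y) < 2L) {
    mp_abort("training labels must contain both classes", "mp_design_error")
  }
  fit <- fit_forest_raw(x, y, trees, seed)
  structure(list(model = fit, probes = colnames(x), trees = trees, seed = seed),
            class = "meth_rf")
}

#' @rdname train_forest
#' @param classifier A `meth_rf` from [train_forest()].
#' @export
predict_forest <- function(classifier, features) {
  if (!inherits(classifier, "meth_rf")) {
    mp_abort("`classifier` must come from train_forest()", "mp_validation_error")
  }
  x <- feature_values(features)
  missing_probes <- setdiff(classifier$probes, colnames(x))
  if (length(missing_probes)) {
    mp_abort(sprintf("features are missing probe(s): %s",
                     paste(missing_probes, collapse = ", ")),
             "mp_validation_error")
  }
  as.character(predict_raw(classifier$model,
                           x[, classifier$probes, drop = FALSE]))
}

#' Confusion counts, accuracy and Cohen's kappa
#'
#' Scores predictions against truth with `"tumor"` as the positive class.
#' `accuracy = (TP + TN) / n`; `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` computed from the confusion-matrix marginals.
#' When `p_e = 1` (both sides constant and equal) kappa is undefined and
#' flagged.
#'
#' @param predictions,truth Equal-length label vectors.
#' @return An `eval_report`: list with `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `kappa`, `kappa_undefined`, `n_test`.
#' @export
evaluate <- function(predictions, truth) {
  if (length(predictions) != length(truth) || length(truth) < 1L) {
    mp_abort("`predictions` and `truth` must have equal length >= 1",
             "mp_validation_error")
  }
  pred <- as_group_factor(predictions)
  obs <- as_group_factor(truth)
  stats <- agreement_stats(pred, obs)
  structure(list(tp = sum(pred == "tumor" & obs == "tumor"),
                 fp = sum(pred == "tumor" & obs == "normal"),
                 fn = sum(pred == "normal" & obs == "tumor"),
                 tn = sum(pred == "normal" & obs == "normal"),
                 accuracy = stats$accuracy,
                 kappa = stats$kappa,
                 kappa_undefined = is.na(stats$kappa),
                 n_test = stats$n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  accuracy=%.4f  kappa=%s\n", x$n_test,
              x$accuracy,
              if (x$kappa_undefined) "undefined" else sprintf("%.4f", x$kappa)))
  cat(sprintf("  TP=%d FP=%d FN=%d TN=%d (positive class: tumor)\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' External validation of a marker panel on a new cohort
#'
#' Full validation protocol for an independent (typically imbalanced) cohort:
#' the panel probes are re-binarized from the new cohort's own values, the
#' cohort is split stratified 80/20, the training side is rebalanced by
#' [rose_oversample()] (the held-out test side is never rebalanced), a fresh
#' seeded forest is trained, and the untouched test samples are scored.
#'
#' @param new_matrix A [meth_matrix()] for the validation cohort.
#' @param new_sheet Its sample sheet.
#' @param panel A `meth_panel` (or list with a `probes` element).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param trees Trees of the validation forest (default 500).
#' @param seed Integer seed; the split, the oversampler and the forest use
#'   seeds derived from it.
#' @return An `eval_report` with an extra `n_train` element.
#' @export
validate_external <- function(new_matrix, new_sheet, panel,
                              test_fraction = 0.2, trees = 500L, seed = 1L) {
  probes <- panel$probes
  if (is.null(probes) || !length(probes)) {
    mp_abort("`panel` has no probes", "mp_validation_error")
  }
  features <- rebinarize_panel(new_matrix, probes)
  sheet <- align_sheet(new_matrix, new_sheet)
  split <- train_test_split(sheet$sample_id, sheet$group,
                            test_fraction = test_fraction, seed = seed + 1L)
  x <- feature_values(features)
  lab <- stats::setNames(sheet$group, sheet$sample_id)
  balanced <- rose_oversample(x[split$train, , drop = FALSE],
                              lab[split$train], seed = seed + 2L)
  classifier <- train_forest(balanced$features, balanced$labels,
                             trees = trees, seed = seed + 3L)
  pred <- predict_forest(classifier, x[split$test, , drop = FALSE])
  report <- evaluate(pred, lab[split$test])
  report$n_train <- length(split$train)
  report
}
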