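#' Panel-selection configuration
#'
#' Bundles the tunables of importance ranking and greedy panel construction:
#' the pairwise correlation cap of admitted probes (0.7), the number of
#' stratified CV folds (10), forest size (500 trees), the fraction of
#' remaining features eliminated per RFE round (0.2), and the seed all
#' stochastic steps derive from.
#'
#' @param corr_threshold Admission cap on |phi| with the current panel, (0, 1].
#' @param folds CV folds, >= 2.
#' @param trees Trees per random forest, >= 1.
#' @param elimination_fraction Fraction of remaining features dropped per RFE
#'   round, in (0, 1).
#' @param seed Integer seed.
#' @return A `selection_config` list.
#' @export
selection_config <- function(corr_threshold = 0.7, folds = 10L, trees = 500L,
                             elimination_fraction = 0.2, seed = 1L) {
  if (!is.numeric(corr_threshold) || length(corr_threshold) != 1L ||
      corr_threshold <= 0 || corr_threshold > 1) {
    mp_abort("`corr_threshold` must lie in (0, 1]", "mp_config_error")
  }
  if (!is.numeric(folds) || length(folds) != 1L || folds < 2 ||
      folds != floor(folds)) {
    mp_abort("`folds` must be an integer >= 2", "mp_config_error")
  }
  if (!is.numeric(trees) || length(trees) != 1L || trees < 1) {
    mp_abort("`trees` must be >= 1", "mp_config_error")
  }
  if (!is.numeric(elimination_fraction) || length(elimination_fraction) != 1L ||
      elimination_fraction <= 0 || elimination_fraction >= 1) {
    mp_abort("`elimination_fraction` must lie in (0, 1)", "mp_config_error")
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != floor(seed)) {
    mp_abort("`seed` must be an integer", "mp_config_error")
  }
  structure(list(corr_threshold = corr_threshold, folds = as.integer(folds),
                 trees = as.integer(trees),
                 elimination_fraction = elimination_fraction,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Phi coefficient of two binary vectors
#'
#' The Pearson correlation computed on 0/1 values.
#'
#' @param x,y Binary vectors of equal length >= 2, neither constant.
#' @return A number in `[-1, 1]`.
#' @export
phi_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    mp_abort("`x` and `y` must have equal length >= 2", "mp_validation_error")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    mp_abort("phi is undefined for a constant vector", "mp_validation_error")
  }
  as.numeric(stats::cor(x, y))
}

# Deterministic stratified fold assignment: shuffle within class under the
# seed, then deal folds round-robin.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Pooled accuracy and Cohen's kappa of a prediction/truth pair.
agreement_stats <- function(predictions, truth) {
  pred <- as_group_factor(predictions)
  obs <- as_group_factor(truth)
  n <- length(obs)
  p_o <- mean(pred == obs)
  p_e <- mean(pred == "tumor") * mean(obs == "tumor") +
    mean(pred == "normal") * mean(obs == "normal")
  kappa <- if (p_e == 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  list(accuracy = p_o, kappa = kappa, n = n)
}

# A forest cannot split on an all-constant feature matrix (and the ensemble
# backend loops forever on one), so degenerate training data collapses to the
# majority vote its trees would return anyway.
fit_forest_raw <- function(x, y, trees, seed) {
  if (all(x == rep(x[1L, ], each = nrow(x)))) {
    tab <- table(y)
    maj <- names(tab)[which.max(tab)]
    return(structure(list(majority = maj, levels = levels(y)),
                     class = "majority_vote"))
  }
  withr::with_seed(seed, {
    randomForest::randomForest(x = x, y = y, ntree = trees)
  })
}

predict_raw <- function(fit, x) {
  if (inherits(fit, "majority_vote")) {
    return(factor(rep(fit$majority, nrow(x)), levels = fit$levels))
  }
  stats::predict(fit, x)
}

#' Stratified k-fold cross-validation of a random forest
#'
#' Assigns folds stratified by class under the config seed, fits one seeded
#' forest per fold, pools the out-of-fold predictions, and scores them once
#' for accuracy and Cohen's kappa. If a class is rarer than the requested
#' fold count the number of folds is reduced (minimum 2) with a warning, so
#' every training split contains both classes.
#'
#' @param features Samples-by-features 0/1 matrix (or `binary_features`).
#' @param labels Tumor/normal labels parallel to the rows.
#' @param config A [selection_config()].
#' @return List with `accuracy`, `kappa` and `n`.
#' @export
cross_validate <- function(features, labels, config = selection_config()) {
  x <- feature_values(features)
  y <- as_group_factor(labels)
  if (length(y) != nrow(x)) {
    mp_abort("labels must parallel the feature rows", "mp_validation_error")
  }
  if (nlevels(droplevels(y)) < 2L) {
    mp_abort("both classes must be present", "mp_design_error")
  }
  if (config$folds > nrow(x)) {
    mp_abort("more folds than samples", "mp_validation_error")
  }
  k <- min(config$folds, min(table(y)))
  if (k < config$folds) {
    mp_warn(sprintf("reducing folds from %d to %d so both classes appear in training",
                    config$folds, max(k, 2L)), "mp_fold_warning")
  }
  k <- max(k, 2L)
  fold <- stratified_folds(y, k, config$seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (i in seq_len(k)) {
    test <- fold == i
    fit <- fit_forest_raw(x[!test, , drop = FALSE], droplevels(y[!test]),
                          config$trees, config$seed + i)
    pred[test] <- predict_raw(fit, x[test, , drop = FALSE])
  }
  agreement_stats(pred, y)
}

#' Rank probes by random-forest recursive feature elimination
#'
#' Iteratively fits a seeded random forest on the surviving features, scores
#' each by out-of-bag permutation importance (mean decrease in accuracy), and
#' eliminates the least important `ceiling(elimination_fraction * remaining)`
#' features, until one survives. The final ranking is the reverse elimination
#' order; within an elimination round, ties are broken by importance
#' (descending) and then probe id.
#'
#' @inheritParams cross_validate
#' @return An `importance_ranking` data frame with columns `probe_id`,
#'   `importance` (score when eliminated or at the final fit) and
#'   `elim_round` (0 for the survivor).
#' @export
rf_importance_ranking <- function(features, labels, config = selection_config()) {
  x <- feature_values(features)
  y <- as_group_factor(labels)
  if (nlevels(droplevels(y)) < 2L) {
    mp_abort("both classes must be present", "mp_design_error")
  }
  if (ncol(x) < 2L) {
    mp_abort("need at least 2 features to rank", "mp_validation_error")
  }
  remaining <- colnames(x)
  rows <- list()
  round <- 0L
  while (length(remaining) > 1L) {
    round <- round + 1L
    fit <- withr::with_seed(config$seed + 1000L + round, {
      randomForest::randomForest(x = x[, remaining, drop = FALSE], y = y,
                                 ntree = config$trees, importance = TRUE)
    })
    imp <- randomForest::importance(fit, type = 1L)[, 1L]
    n_drop <- min(ceiling(config$elimination_fraction * length(remaining)),
                  length(remaining) - 1L)
    # among equal importances, drop lexicographically later ids first so the
    # retained ranking ends up id-ascending within ties
    ord <- order(imp, -xtfrm(remaining))
    drop <- remaining[ord[seq_len(n_drop)]]
    rows[[round]] <- data.frame(probe_id = drop,
                                importance = unname(imp[drop]),
                                elim_round = round,
                                stringsAsFactors = FALSE)
    survivor_imp <- imp
    remaining <- setdiff(remaining, drop)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    probe_id = remaining,
    importance = if (exists("survivor_imp")) unname(survivor_imp[remaining]) else NA_real_,
    elim_round = 0L, stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  # survivor first (round 0 coded as +Inf rank), then later rounds first
  key <- ifelse(tab$elim_round == 0L, Inf, tab$elim_round)
  tab <- tab[order(-key, -tab$importance, tab$probe_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("importance_ranking", "data.frame")
  tab
}

#' Greedy correlation-filtered panel construction
#'
#' Walks the importance ranking from the top. The first probe is always
#' admitted; a later probe is admitted only if its absolute phi correlation
#' with every probe already in the panel is below `corr_threshold`, so
#' redundant probes (for methylation arrays: CpGs carrying the same regional
#' signal) are skipped. After each admission the current prefix is scored by
#' [cross_validate()].
#'
#' @param ranking An `importance_ranking` (or anything with `probe_id`).
#' @inheritParams cross_validate
#' @return List with `trace` (data frame `n_features`, `probe_id`,
#'   `cv_accuracy`, `cv_kappa`), `admitted` and `skipped` probe ids.
#' @export
greedy_panel_build <- function(ranking, features, labels,
                               config = selection_config()) {
  x <- feature_values(features)
  ids <- ranking$probe_id
  if (!all(ids %in% colnames(x))) {
    mp_abort("ranking refers to probes absent from the features",
             "mp_validation_error")
  }
  admitted <- character(0)
  skipped <- character(0)
  trace <- list()
  for (p in ids) {
    if (length(admitted) > 0L) {
      phis <- vapply(admitted,
                     function(q) abs(phi_correlation(x[, p], x[, q])),
                     numeric(1))
      if (max(phis) >= config$corr_threshold) {
        skipped <- c(skipped, p)
        next
      }
    }
    admitted <- c(admitted, p)
    cv <- cross_validate(x[, admitted, drop = FALSE], labels, config)
    trace[[length(trace) + 1L]] <- data.frame(
      n_features = length(admitted), probe_id = p,
      cv_accuracy = cv$accuracy, cv_kappa = cv$kappa,
      stringsAsFactors = FALSE)
  }
  list(trace = do.call(rbind, trace), admitted = admitted, skipped = skipped)
}

#' Choose the final panel size from a CV trace
#'
#' Returns the prefix size with the best cross-validated accuracy; ties are
#' broken by higher kappa, then by the smaller (more parsimonious) prefix.
#'
#' @param trace The trace from [greedy_panel_build()].
#' @return The chosen prefix size (row's `n_features`).
#' @export
choose_final_panel <- function(trace) {
  if (is.null(trace) || nrow(trace) == 0L) {
    mp_abort("empty panel trace", "mp_validation_error")
  }
  best <- which(trace$cv_accuracy == max(trace$cv_accuracy))
  kap <- trace$cv_kappa[best]
  kap[is.na(kap)] <- -Inf
  best <- best[kap == max(kap)]
  trace$n_features[min(best)]
}

#' Build a marker panel end to end
#'
#' [rf_importance_ranking()], [greedy_panel_build()], [choose_final_panel()],
#' then a final seeded forest on the chosen probes over all samples. The
#' pairwise-phi admission invariant is asserted on the result.
#'
#' @param features A `binary_features` object from [binarize_matrix()].
#' @inheritParams cross_validate
#' @return A `meth_panel`: list with `probes`, `splits`, `trace`,
#'   `candidate_order`, `size`, `cv_accuracy`, `cv_kappa`, `classifier` and
#'   `config`.
#' @export
build_panel <- function(features, labels, config = selection_config()) {
  ranking <- rf_importance_ranking(features, labels, config)
  built <- greedy_panel_build(ranking, features, labels, config)
  size <- choose_final_panel(built$trace)
  probes <- built$admitted[seq_len(size)]
  x <- feature_values(features)
  if (length(probes) > 1L) {
    pairs <- utils::combn(probes, 2L)
    phis <- apply(pairs, 2L, function(pr)
      abs(phi_correlation(x[, pr[1]], x[, pr[2]])))
    stopifnot(all(phis < config$corr_threshold))
  }
  classifier <- train_forest(x[, probes, drop = FALSE], labels,
                             trees = config$trees, seed = config$seed)
  chosen <- built$trace[built$trace$n_features == size, , drop = FALSE]
  splits <- if (inherits(features, "binary_features")) {
    features$splits[features$splits$probe_id %in% probes, , drop = FALSE]
  } else {
    NULL
  }
  structure(list(probes = probes, splits = splits, trace = built$trace,
                 candidate_order = built$admitted, size = size,
                 cv_accuracy = chosen$cv_accuracy, cv_kappa = chosen$cv_kappa,
                 classifier = classifier, config = config),
            class = "meth_panel")
}

#' @export
print.meth_panel <- function(x, ...) {
  cat(sprintf("<meth_panel> %d probe(s): %s\n", x$size,
              paste(x$probes, collapse = ", ")))
  cat(sprintf("  CV accuracy %.3f, kappa %.3f\n", x$cv_accuracy, x$cv_kappa))
  invisible(x)
}
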