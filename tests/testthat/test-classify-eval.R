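test_that("stratified split preserves class ratios and is seeded", {
  ids <- sprintf("s%03d", 1:100)
  labels <- rep(c("tumor", "normal"), c(80, 20))
  sp <- train_test_split(ids, labels, test_fraction = 0.2, seed = 5)
  expect_length(sp$test, 20L)
  expect_length(sp$train, 80L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_equal(sum(sp$test %in% ids[1:80]), 16L)   # 16 tumor + 4 normal

  sp2 <- train_test_split(ids, labels, test_fraction = 0.2, seed = 5)
  expect_identical(sp, sp2)

  half <- train_test_split(sprintf("x%d", 1:8),
                           rep(c("tumor", "normal"), each = 4),
                           test_fraction = 0.5, seed = 1)
  expect_length(half$test, 4L)

  expect_error(train_test_split(c("a", "b", "c"), c("tumor", "tumor", "normal")),
               class = "mp_split_error")
})

test_that("the smoothed-bootstrap bandwidth follows its closed form", {
  expect_equal(rose_bandwidth(1, 100, 1), (4 / 300)^(1 / 5))
  expect_equal(rose_bandwidth(1, 100, 1), 0.4217, tolerance = 1e-3)
  expect_equal(rose_bandwidth(4, 25, 0.5), 0.3179, tolerance = 1e-3)
  expect_equal(rose_bandwidth(3, 10, 0), 0)
  expect_error(rose_bandwidth(0, 10, 1), class = "mp_config_error")
})

test_that("oversampling balances classes without touching originals", {
  cohort <- binary_cohort(n_tumor = 15, n_normal = 5, good = 2, flips = 4,
                          seed = 2)
  out <- rose_oversample(cohort$x, cohort$labels, seed = 11)
  expect_equal(as.vector(table(out$labels)), c(15L, 15L))
  expect_identical(out$features[1:20, ], cohort$x)
  expect_true(all(out$features %in% c(0L, 1L)))
  expect_equal(nrow(out$features), 30L)

  balanced <- binary_cohort(n_tumor = 10, n_normal = 10, seed = 3)
  noop <- rose_oversample(balanced$x, balanced$labels, seed = 1)
  expect_identical(noop$features, balanced$x)
})

test_that("synthetic minority samples preserve the minority feature means", {
  # continuous features make the kernel-smoothing property exact
  withr::with_seed(8, {
    x <- cbind(f1 = c(rnorm(30, 2), rnorm(10, 0)),
               f2 = c(rnorm(30, -1), rnorm(10, 1)))
    rownames(x) <- sprintf("s%02d", 1:40)
  })
  labels <- rep(c("tumor", "normal"), c(30, 10))
  minority_means <- colMeans(x[31:40, ])
  minority_sd <- apply(x[31:40, ], 2, sd)
  syn_means <- matrix(NA_real_, 50, 2)
  for (r in 1:50) {
    out <- rose_oversample(x, labels, seed = r, binary = FALSE)
    syn_means[r, ] <- colMeans(out$features[41:60, ])
  }
  se <- minority_sd / sqrt(20)
  expect_lt(abs(mean(syn_means[, 1]) - minority_means[1]), 3 * se[1] / sqrt(50))
  expect_lt(abs(mean(syn_means[, 2]) - minority_means[2]), 3 * se[2] / sqrt(50))
})

test_that("a single-sample minority falls back to duplication with a warning", {
  x <- cbind(f1 = c(1L, 1L, 1L, 0L), f2 = c(1L, 0L, 1L, 0L))
  rownames(x) <- sprintf("s%d", 1:4)
  labels <- c("tumor", "tumor", "tumor", "normal")
  expect_warning(out <- rose_oversample(x, labels, seed = 1),
                 class = "mp_degenerate_warning")
  expect_equal(sum(out$labels == "normal"), 3L)
  expect_true(all(out$features[out$labels == "normal", "f1"] == 0L))
})

test_that("forest training is seeded, reproducible and sane on edge cases", {
  cohort <- binary_cohort(n_tumor = 25, n_normal = 25, seed = 5)
  fit <- train_forest(cohort$x, cohort$labels, trees = 100, seed = 4)
  expect_identical(predict_forest(fit, cohort$x), cohort$labels)

  fit2 <- train_forest(cohort$x, cohort$labels, trees = 100, seed = 4)
  grid <- matrix(c(0L, 1L), ncol = 1, dimnames = list(c("g1", "g2"), "good1"))
  expect_identical(predict_forest(fit, grid), predict_forest(fit2, grid))

  expect_error(train_forest(cohort$x, rep("tumor", 50)),
               class = "mp_design_error")

  # indistinguishable rows with mixed labels: majority vote wins
  x <- matrix(1L, nrow = 10, ncol = 1,
              dimnames = list(sprintf("s%d", 1:10), "f"))
  labels <- rep(c("tumor", "normal"), c(7, 3))
  maj <- train_forest(x, labels, trees = 200, seed = 1)
  expect_true(all(predict_forest(maj, x) == "tumor"))
})

test_that("evaluation reproduces hand-computed confusion statistics", {
  perfect <- evaluate(rep(c("tumor", "normal"), 5), rep(c("tumor", "normal"), 5))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)

  truth <- rep(c("tumor", "normal"), c(50, 50))
  pred <- c(rep("tumor", 40), rep("normal", 10),   # 40 TP, 10 FN
            rep("tumor", 5), rep("normal", 45))    # 5 FP, 45 TN
  r <- evaluate(pred, truth)
  expect_equal(c(r$tp, r$fp, r$fn, r$tn), c(40L, 5L, 10L, 45L))
  expect_equal(r$accuracy, 0.85)
  expect_equal(r$kappa, 0.7)

  one_sided <- evaluate(rep("tumor", 10), rep(c("tumor", "normal"), each = 5))
  expect_equal(one_sided$kappa, 0)

  expect_error(evaluate(c("tumor"), c("tumor", "normal")),
               class = "mp_validation_error")
})

test_that("kappa matches a brute-force recomputation on random label pairs", {
  withr::with_seed(55, {
    for (i in 1:100) {
      n <- sample(2:100, 1)
      pred <- sample(c("tumor", "normal"), n, replace = TRUE)
      truth <- sample(c("tumor", "normal"), n, replace = TRUE)
      r <- evaluate(pred, truth)
      k <- kappa_oracle(pred, truth)
      if (is.na(k)) {
        expect_true(r$kappa_undefined)
      } else {
        expect_equal(r$kappa, k)
      }
    }
  })
})

test_that("external validation runs the full protocol and flags missing probes", {
  cfg <- simulation_config(n_tumor = 60, n_normal = 40, n_probes = 30,
                           n_signal_blocks = 2, block_size = 2, effect_m = 3,
                           precision = 300, seed = 19)
  sim <- simulate_cohort(cfg)
  panel <- list(probes = sim$ground_truth$probe_id[c(1, 3)])
  rep1 <- validate_external(beta_to_m(sim$matrix), sim$sheet, panel,
                            trees = 100, seed = 3)
  expect_s3_class(rep1, "eval_report")
  expect_equal(rep1$n_test + rep1$n_train, 100L)
  expect_gt(rep1$accuracy, 0.9)

  expect_error(validate_external(sim$matrix, sim$sheet,
                                 list(probes = "cg99999999")),
               class = "mp_validation_error")
  expect_error(validate_external(sim$matrix, sim$sheet, list(probes = NULL)),
               class = "mp_validation_error")
})

test_that("test predictions are invariant to the oversampling seed when separable", {
  cfg <- simulation_config(n_tumor = 80, n_normal = 20, n_probes = 10,
                           n_signal_blocks = 2, block_size = 1, effect_m = 4,
                           within_block_noise_m = 0.05, precision = 500,
                           seed = 29)
  sim <- simulate_cohort(cfg)
  m <- beta_to_m(sim$matrix)
  probes <- sim$ground_truth$probe_id[1:2]
  feats <- rebinarize_panel(m, probes)
  sp <- train_test_split(sim$sheet$sample_id, sim$sheet$group, seed = 1)
  lab <- stats::setNames(sim$sheet$group, sim$sheet$sample_id)
  accs <- vapply(1:5, function(rs) {
    bal <- rose_oversample(feats$values[sp$train, ], lab[sp$train], seed = rs)
    fit <- train_forest(bal$features, bal$labels, trees = 100, seed = 7)
    evaluate(predict_forest(fit, feats$values[sp$test, ]), lab[sp$test])$accuracy
  }, numeric(1))
  expect_equal(length(unique(accs)), 1L)
})
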