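test_that("phi correlation matches hand-computed binary cases", {
  x <- c(1, 1, 0, 0)
  expect_equal(phi_correlation(x, x), 1)
  expect_equal(phi_correlation(x, c(1, 0, 1, 0)), 0)
  expect_equal(phi_correlation(x, c(0, 0, 1, 1)), -1)
  expect_error(phi_correlation(x, c(1, 1, 1, 1)), class = "mp_validation_error")
  expect_error(phi_correlation(x, c(1, 0)), class = "mp_validation_error")
})

test_that("selection config rejects out-of-range tunables", {
  expect_error(selection_config(folds = 1), class = "mp_config_error")
  expect_error(selection_config(corr_threshold = 0), class = "mp_config_error")
  expect_error(selection_config(elimination_fraction = 1), class = "mp_config_error")
})

test_that("cross-validation scores a perfect marker perfectly and errors sanely", {
  cohort <- binary_cohort(n_tumor = 20, n_normal = 20)
  cfg <- selection_config(folds = 5, trees = 50, seed = 3)
  cv <- cross_validate(cohort$x, cohort$labels, cfg)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$kappa, 1)

  four <- c(1:2, 21:22)  # two tumors, two normals
  expect_error(cross_validate(cohort$x[four, , drop = FALSE],
                              cohort$labels[four],
                              selection_config(folds = 10, trees = 10)),
               class = "mp_validation_error")
  expect_error(cross_validate(cohort$x, rep("tumor", 40), cfg),
               class = "mp_design_error")
})

test_that("cross-validated kappa is centred on zero for uninformative features", {
  kappas <- numeric(20)
  for (r in 1:20) {
    withr::with_seed(100 + r, {
      x <- matrix(stats::rbinom(40 * 2, 1, 0.5), ncol = 2,
                  dimnames = list(sprintf("s%02d", 1:40), c("f1", "f2")))
      labels <- rep(c("tumor", "normal"), each = 20)
    })
    cv <- cross_validate(x, labels, selection_config(folds = 4, trees = 50,
                                                     seed = r))
    kappas[r] <- cv$kappa
  }
  expect_lt(abs(mean(kappas)), 0.15)
})

test_that("RFE ranks a class-determining feature above independent noise", {
  for (seed in 1:5) {
    cohort <- binary_cohort(n_tumor = 50, n_normal = 50, good = 1, noise = 20,
                            flips = 0, seed = seed)
    rk <- rf_importance_ranking(cohort$x, cohort$labels,
                                selection_config(trees = 100, seed = seed))
    expect_equal(rk$probe_id[1], "good1")
    expect_setequal(rk$probe_id, colnames(cohort$x))
    expect_false(anyDuplicated(rk$probe_id) > 0)
  }
})

test_that("duplicated informative features both outrank noise", {
  cohort <- binary_cohort(n_tumor = 50, n_normal = 50, good = 2, noise = 10,
                          flips = 3, seed = 4)
  rk <- rf_importance_ranking(cohort$x, cohort$labels,
                              selection_config(trees = 100, seed = 4))
  expect_setequal(rk$probe_id[1:2], c("good1", "good2"))
})

test_that("RFE of two features returns a permutation of both", {
  cohort <- binary_cohort(n_tumor = 15, n_normal = 15, good = 1, noise = 1,
                          seed = 6)
  rk <- rf_importance_ranking(cohort$x, cohort$labels,
                              selection_config(trees = 50, seed = 6))
  expect_setequal(rk$probe_id, c("good1", "noise01"))
})

test_that("greedy build admits by the correlation filter in ranking order", {
  # A/B nearly identical, C independent of A, D nearly identical to C
  n <- 40
  A <- rep(c(1L, 0L), each = n / 2)
  B <- A; B[c(1, 21)] <- 1L - B[c(1, 21)]
  C <- rep(c(1L, 0L), times = n / 2)
  D <- C; D[c(2, 22)] <- 1L - D[c(2, 22)]
  x <- cbind(A = A, B = B, C = C, D = D)
  rownames(x) <- sprintf("s%02d", 1:n)
  stopifnot(abs(phi_correlation(A, B)) >= 0.7,
            abs(phi_correlation(A, C)) < 0.7,
            abs(phi_correlation(A, D)) < 0.7,
            abs(phi_correlation(C, D)) >= 0.7)
  labels <- ifelse(A == 1L, "tumor", "normal")
  ranking <- data.frame(probe_id = c("A", "B", "C", "D"))
  cfg <- selection_config(folds = 4, trees = 50, seed = 2)
  built <- greedy_panel_build(ranking, x, labels, cfg)
  expect_equal(built$admitted, c("A", "C"))
  expect_equal(built$skipped, c("B", "D"))
  expect_equal(built$trace$n_features, 1:2)

  # a vacuous threshold admits every probe
  all_in <- greedy_panel_build(ranking, x, labels,
                               selection_config(corr_threshold = 1,
                                                folds = 4, trees = 50, seed = 2))
  expect_equal(all_in$admitted, c("A", "B", "C", "D"))

  single <- greedy_panel_build(data.frame(probe_id = "A"),
                               x[, "A", drop = FALSE], labels, cfg)
  expect_equal(nrow(single$trace), 1L)
})

test_that("final panel size maximises accuracy with kappa and parsimony tie-breaks", {
  trace <- data.frame(n_features = 1:3,
                      cv_accuracy = c(0.80, 0.92, 0.92),
                      cv_kappa = c(0.55, 0.83, 0.82))
  expect_equal(choose_final_panel(trace), 2L)

  rising <- data.frame(n_features = 1:4, cv_accuracy = c(0.7, 0.8, 0.9, 0.95),
                       cv_kappa = 0.5)
  expect_equal(choose_final_panel(rising), 4L)
  expect_equal(choose_final_panel(rising[1, ]), 1L)

  tied <- data.frame(n_features = 1:2, cv_accuracy = 0.9, cv_kappa = 0.7)
  expect_equal(choose_final_panel(tied), 1L)
})

test_that("panel selection is a pure function of features, labels and seed", {
  cohort <- binary_cohort(n_tumor = 30, n_normal = 30, good = 3, noise = 5,
                          flips = 6, seed = 12)
  cfg <- selection_config(folds = 5, trees = 80, seed = 9)
  p1 <- build_panel(cohort$x, cohort$labels, cfg)
  p2 <- build_panel(cohort$x, cohort$labels, cfg)
  expect_identical(p1$probes, p2$probes)
  expect_identical(p1$trace, p2$trace)
  expect_identical(p1$size, p2$size)
})
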