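test_that("per-probe fits match hand-computed group statistics", {
  vals <- matrix(c(1, 3, 0, 0,
                   2, 2, 2, 2,
                   5, 5, 1, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("cgA", "cgB", "cgC"), sprintf("s%d", 1:4)))
  m <- meth_matrix(vals, "M")
  sheet <- sample_sheet(sprintf("s%d", 1:4), c("tumor", "tumor", "normal", "normal"))
  fits <- fit_probe_models(m, sheet)
  expect_equal(fits$logFC, c(2, 0, 4))
  expect_equal(fits$s2_g, c(1, 0, 0))
  expect_equal(fits$d_g, rep(2L, 3))
  expect_equal(fits$v_g, rep(1, 3))

  one_class <- sample_sheet(sprintf("s%d", 1:4), rep("tumor", 4))
  expect_error(fit_probe_models(m, one_class), class = "mp_design_error")
})

test_that("equal observed variances give an infinite-prior moderation", {
  fits <- data.frame(probe_id = sprintf("cg%d", 1:5), logFC = 1:5,
                     s2_g = rep(0.5, 5), d_g = rep(10L, 5), v_g = rep(0.2, 5))
  mod <- estimate_moderation(fits)
  expect_true(is.infinite(mod$d0))
  # every posterior variance collapses onto s0_2: t = logFC / sqrt(s0_2 v)
  tab <- moderated_tests(fits, mod)
  expect_equal(tab$t, fits$logFC / sqrt(mod$s0_2 * fits$v_g))

  all_zero <- transform(fits, s2_g = 0)
  expect_error(estimate_moderation(all_zero), class = "mp_estimation_error")
})

test_that("moderated t reduces to the ordinary t in the d0 -> 0 limit", {
  withr::with_seed(9, {
    vals <- matrix(rnorm(20 * 30), nrow = 20,
                   dimnames = list(sprintf("cg%02d", 1:20), sprintf("s%02d", 1:30)))
  })
  m <- meth_matrix(vals, "M")
  sheet <- sample_sheet(sprintf("s%02d", 1:30), rep(c("tumor", "normal"), each = 15))
  fits <- fit_probe_models(m, sheet)
  tab <- moderated_tests(fits, list(d0 = 1e-9, s0_2 = 1))
  ordinary <- fits$logFC / sqrt(fits$s2_g * fits$v_g)
  expect_equal(tab$t, ordinary, tolerance = 1e-6)
  expect_equal(sign(tab$t), sign(fits$logFC))
})

test_that("moderation recovers known hyperparameters and agrees with limma", {
  skip_if_not_installed("limma")
  d0 <- 4; s0_2 <- 0.05; d_g <- 10L; m <- 3000L
  withr::with_seed(17, {
    sigma2 <- d0 * s0_2 / stats::rchisq(m, d0)
    s2 <- sigma2 * stats::rchisq(m, d_g) / d_g
  })
  fits <- data.frame(probe_id = sprintf("cg%05d", seq_len(m)), logFC = 0,
                     s2_g = s2, d_g = d_g, v_g = 1)
  mod <- estimate_moderation(fits)
  expect_lt(abs(mod$d0 - d0) / d0, 0.25)
  expect_lt(abs(mod$s0_2 - s0_2) / s0_2, 0.10)

  ref <- limma::fitFDist(s2, df1 = d_g)
  expect_equal(mod$d0, ref$df2, tolerance = 1e-4)
  expect_equal(mod$s0_2, ref$scale, tolerance = 1e-4)
})

test_that("the full moderated pipeline matches limma on a simulated cohort", {
  skip_if_not_installed("limma")
  cfg <- simulation_config(n_tumor = 10, n_normal = 8, n_probes = 300,
                           n_signal_blocks = 20, effect_m = 1.5, seed = 23)
  sim <- simulate_cohort(cfg)
  m <- beta_to_m(sim$matrix)
  tab <- dmp_analysis(m, sim$sheet)

  grp <- factor(sim$sheet$group, levels = c("normal", "tumor"))
  design <- stats::model.matrix(~grp)
  fit <- limma::eBayes(limma::lmFit(m$values, design))
  ref <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  idx <- match(tab$probe_id, rownames(ref))
  expect_equal(tab$logFC, ref$logFC[idx], tolerance = 1e-10)
  expect_equal(tab$t, ref$t[idx], tolerance = 1e-6)
  expect_equal(tab$p, ref$P.Value[idx], tolerance = 1e-6)
  expect_equal(tab$adj_p, ref$adj.P.Val[idx], tolerance = 1e-6)
})

test_that("BH adjustment matches the hand example and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mp_validation_error")

  withr::with_seed(31, {
    for (i in 1:25) {
      p <- runif(sample(1:50, 1))
      adj <- bh_adjust(p)
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(adj <= 1))
      expect_false(is.unsorted(adj[order(p)]))
    }
  })
})

test_that("DMP calling applies both strict thresholds and sets direction", {
  tab <- data.frame(probe_id = c("a", "b", "c"),
                    symbol = NA_character_,
                    logFC = c(1.2, -0.5, -1.3),
                    t = 0, p = 0,
                    adj_p = c(0.01, 0.001, 0.2),
                    direction = NA_character_)
  called <- call_dmps(tab)
  expect_equal(called$probe_id, "a")
  expect_equal(called$direction, "hyper")
  expect_equal(nrow(call_dmps(tab[0, ])), 0L)
  # boundary values are excluded by the strict comparisons
  edge <- transform(tab, logFC = c(1.0, 2, 2), adj_p = c(0.01, 0.05, 0.01))
  expect_equal(call_dmps(edge)$probe_id, "c")
})

test_that("DMP summaries report counts and extreme records", {
  tab <- load_table2_fixture()
  s <- summarize_dmps(tab)
  expect_equal(s$n_total, 62L)
  expect_equal(s$n_hyper, 59L)
  expect_equal(s$n_hypo, 3L)
  expect_equal(s$max_logfc$probe_id, "cg08089301")
  expect_equal(s$max_logfc$logFC, 1.55)
  expect_equal(s$min_logfc$logFC, -1.07)
  expect_equal(s$top$probe_id, "cg26521404")

  empty <- summarize_dmps(tab[0, ])
  expect_equal(empty$n_total, 0L)
  expect_null(empty$top)
})

test_that("DMP tables sort by adjusted p with |logFC| and id tie-breaks", {
  tab <- data.frame(probe_id = c("cgB", "cgA", "cgC"),
                    symbol = NA_character_,
                    logFC = c(1.0, -2.0, 2.0),
                    t = 0, p = 0,
                    adj_p = c(0.01, 0.01, 0.01),
                    direction = NA_character_)
  expect_equal(sort_dmp_table(tab)$probe_id, c("cgA", "cgC", "cgB"))
})
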