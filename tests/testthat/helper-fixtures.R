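# Small in-code fixtures shared across test files.

tiny_beta_matrix <- function(values = c(0.10, 0.90, 0.20, 0.80, 0.30, 0.70),
                             nrow = 3L,
                             probes = sprintf("cg%02d", seq_len(nrow)),
                             samples = sprintf("s%d", seq_len(length(values) / nrow)),
                             space = "beta") {
  meth_matrix(matrix(values, nrow = nrow, dimnames = list(probes, samples)),
              space)
}

# A clean two-class cohort of binary features: `good` columns equal the class
# indicator with `flips` random disagreements, `noise` columns are coin flips.
binary_cohort <- function(n_tumor = 50L, n_normal = 50L, good = 1L,
                          noise = 0L, flips = 0L, seed = 1L) {
  n <- n_tumor + n_normal
  labels <- c(rep("tumor", n_tumor), rep("normal", n_normal))
  withr::with_seed(seed, {
    cols <- list()
    base <- as.integer(labels == "tumor")
    for (g in seq_len(good)) {
      f <- base
      if (flips > 0L) {
        idx <- sample.int(n, flips)
        f[idx] <- 1L - f[idx]
      }
      cols[[sprintf("good%d", g)]] <- f
    }
    for (k in seq_len(noise)) {
      cols[[sprintf("noise%02d", k)]] <- stats::rbinom(n, 1L, 0.5)
    }
    x <- do.call(cbind, cols)
    rownames(x) <- sprintf("s%03d", seq_len(n))
    list(x = x, labels = labels)
  })
}
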