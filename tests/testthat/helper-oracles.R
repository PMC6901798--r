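# Independent brute-force oracles used to check the fast implementations.

# Exhaustive 1-D two-means: score every split between distinct adjacent
# sorted values by directly computed within-cluster sums of squares.
# Same tie rule as the implementation (larger low cluster).
brute_two_means <- function(values) {
  s <- sort(values)
  n <- length(s)
  w <- rep(Inf, n - 1L)
  for (i in seq_len(n - 1L)) {
    if (s[i] == s[i + 1L]) next
    low <- s[seq_len(i)]
    high <- s[seq.int(i + 1L, n)]
    w[i] <- sum((low - mean(low))^2) + sum((high - mean(high))^2)
  }
  tol <- 1e-8 * max(1, sum((s - mean(s))^2))
  best_i <- max(which(w <= min(w) + tol))
  thr <- (s[best_i] + s[best_i + 1L]) / 2
  list(threshold = thr, labels = as.integer(values > thr), wcss = w[best_i])
}

# O(m^2) min-over-tail Benjamini-Hochberg.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Cohen's kappa recomputed from the raw label pairs via the count identity
# kappa = (n * sum(diag) - sum(r_i c_i)) / (n^2 - sum(r_i c_i)).
kappa_oracle <- function(pred, truth) {
  lv <- c("normal", "tumor")
  tab <- table(factor(pred, lv), factor(truth, lv))
  n <- sum(tab)
  chance <- sum(rowSums(tab) * colSums(tab))
  if (n^2 == chance) return(NA_real_)
  (n * sum(diag(tab)) - chance) / (n^2 - chance)
}
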