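# Independent oracles used by property and acceptance tests. These stay
# deliberately naive (double loops, repeated squaring, pairwise counts) and
# never call the implementation paths they check.

# KS statistic by exhaustive evaluation of both ECDFs at every pooled point
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  gaps <- vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1))
  max(gaps)
}

# stationary vector by brute-force repeated squaring: rows of P^(2^m)
# converge to pi for a strictly positive chain
oracle_stationary <- function(P, m = 40L) {
  Q <- P
  for (i in seq_len(m)) {
    Q_new <- Q %*% Q
    Q_new <- Q_new / rowSums(Q_new)  # fight drift
    if (max(abs(Q_new - Q)) < 1e-15) break
    Q <- Q_new
  }
  colMeans(Q)
}

# AUC as the normalised Mann-Whitney U: pairwise comparison counts
oracle_auc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# random sparse-ish nonnegative count matrix (27 x 27 by default)
random_counts <- function(k = 27L, lambda = 3, sparsity = 0.6) {
  m <- matrix(stats::rpois(k * k, lambda), k, k)
  m[stats::runif(k * k) < sparsity] <- 0L
  m
}

# random strictly positive row-stochastic matrix
random_stochastic <- function(k = 27L) {
  m <- matrix(stats::rgamma(k * k, shape = 0.8) + 1e-6, k, k)
  m / rowSums(m)
}
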