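# Independent oracles and small fixture builders used across the suite.

# Brute-force topological overlap: explicit triple loop, no linear algebra.
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  out
}

# random valid adjacency (symmetric, [0,1], unit diagonal)
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Independent BH step-up: sort, cumulative minimum from the largest rank.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, K) draws.
hyper_enum_oracle <- function(k, m, big_n, big_k) {
  draws <- utils::combn(big_n, big_k)
  marked <- seq_len(m)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked) >= k)
  mean(hits)
}

# Sample partial correlation of x and y given z.
partial_cor <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Likelihood-ratio chi-square for one vanishing partial correlation.
neo_chi2_oracle <- function(x, y, z) {
  n <- length(x)
  rp <- partial_cor(x, y, z)
  -(n - 1) * log(1 - rp^2)
}

# Data whose *sample* correlation matrix equals R exactly.
exact_moment_data <- function(n, R) {
  x <- matrix(stats::rnorm(n * ncol(R)), n)
  x <- scale(x, scale = FALSE)
  s <- stats::cov(x)
  x <- x %*% solve(chol(s))          # sample covariance now identity
  x <- x %*% chol(R)
  scale(x) / 1                       # unit sample variance columns
}

# Simulate one marker -> gene -> trait chain (paths p1, p2), n samples.
simulate_chain <- function(n, p1 = 0.5, p2 = 0.5) {
  m <- scale(stats::rbinom(n, 2, 0.5))[, 1]
  g <- p1 * m + sqrt(1 - p1^2) * stats::rnorm(n)
  tr <- p2 * scale(g)[, 1] + sqrt(1 - p2^2) * stats::rnorm(n)
  list(marker = m, gene = g, trait = tr)
}

# Small planted-module study shared by several tests.
small_study <- function(seed = 7, n_samples = 90) {
  simulate_network_expression(sim_config(
    n_samples = n_samples,
    module_sizes = c(120L, 100L, 80L, 60L, 50L),
    within_module_cor = 0.7,
    n_background_genes = 300L,
    n_reactive_genes = 15L,
    a1 = 0.5, a2 = 0.5, b = 0.5,
    seed = seed
  ))
}
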