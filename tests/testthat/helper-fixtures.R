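# Shared fixtures and independent oracles for the test suite.

# Random symmetric connectivity matrix with distinct weights.
rand_conn <- function(n, seed = 1, band = "alpha") {
  set.seed(seed)
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  connectivity_matrix(m, band = band)
}

# Hand-built layout at explicit coordinates.
manual_layout <- function(xyz, region = "central") {
  df <- data.frame(label = sprintf("E%03d", seq_len(nrow(xyz))),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   region = rep_len(region, nrow(xyz)),
                   stringsAsFactors = FALSE)
  class(df) <- c("wnet_layout", "data.frame")
  df
}

# All set partitions of 1..n (Bell-number enumeration) — modularity oracle.
all_partitions <- function(n) {
  if (n == 1) return(list(c(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (b in seq_len(max(p) + 1L)) out[[length(out) + 1]] <- c(p, b)
  }
  out
}

# Newman modularity of an explicit partition — independent of the package.
newman_q <- function(adj, membership) {
  w <- sum(adj) / 2
  k <- rowSums(adj)
  q <- 0
  for (cm in unique(membership)) {
    idx <- membership == cm
    q <- q + sum(adj[idx, idx]) / (2 * w) - (sum(k[idx]) / (2 * w))^2
  }
  q
}

# Floyd-Warshall shortest paths — path-length oracle.
floyd_warshall <- function(lengths) {
  n <- nrow(lengths)
  d <- lengths
  d[d == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Spearman rho by rank-then-Pearson with average ties — correlation oracle.
spearman_oracle <- function(x, y) {
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Holm step-down adjustment computed by the definition — correction oracle.
holm_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact two-sided Mann-Whitney p by full enumeration (no ties) — U oracle.
mwu_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, `>`))
  }
  obs <- u_of(seq_len(n1))
  us <- apply(combn(length(pooled), n1), 2, u_of)
  mu <- n1 * (length(b)) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Small two-group cohort on a given layout with per-band attenuation.
quick_cohort <- function(seed, layout, specs, att_a = 1, att_b = 1,
                         band = "alpha", n_a = 8, n_b = 8, n_epochs = 3,
                         fs = 128) {
  atten_a <- setNames(att_a, band)
  atten_b <- setNames(att_b, band)
  generate_cohort(
    list(group_spec("A", n_a, attenuation = atten_a),
         group_spec("B", n_b, attenuation = atten_b)),
    layout, specs, seed = seed, n_epochs = n_epochs, fs = fs)
}
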