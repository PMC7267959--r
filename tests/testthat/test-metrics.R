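bin_graph <- function(adj) {
  dimnames(adj) <- list(sprintf("E%03d", seq_len(nrow(adj))),
                        sprintf("E%03d", seq_len(nrow(adj))))
  structure(list(adjacency = adj, mode = "binary", pt_percent = NA,
                 labels = rownames(adj), band = NA), class = "wnet_graph")
}
wt_graph <- function(adj) {
  g <- bin_graph(adj)
  g$mode <- "weighted"
  g
}
triangle_w <- function(w12 = 1, w13 = 0.5, w23 = 0.25) {
  a <- matrix(0, 3, 3)
  a[1, 2] <- w12; a[1, 3] <- w13; a[2, 3] <- w23
  a + t(a)
}

test_that("degree and strength match hand values and the row-sum oracle", {
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(unname(node_degree(bin_graph(k5))$per_node), rep(4, 5))
  tw <- triangle_w()
  expect_equal(unname(node_degree(wt_graph(tw))$per_node), c(1.5, 1.25, 0.75))
  for (s in 1:5) {
    set.seed(s)
    a <- matrix(runif(49), 7); a <- (a + t(a)) / 2; diag(a) <- 0
    a[a < 0.5] <- 0
    expect_equal(unname(node_degree(wt_graph(a))$per_node), rowSums(a))
    expect_equal(unname(node_degree(bin_graph((a > 0) + 0))$per_node),
                 rowSums(a > 0))
  }
})

test_that("clustering matches closed triangles and an enumeration oracle", {
  tri <- (triangle_w(1, 1, 1) > 0) + 0
  expect_equal(unname(clustering_coef(bin_graph(tri))$per_node), rep(1, 3))
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(unname(clustering_coef(bin_graph(star))$per_node), rep(0, 4))
  # weighted: geometric-mean triangle formula, against explicit enumeration
  tw <- triangle_w()
  got <- clustering_coef(wt_graph(tw))$per_node
  wh <- tw / max(tw)
  for (i in 1:3) {
    js <- setdiff(1:3, i)
    expected <- 2 * (wh[i, js[1]] * wh[i, js[2]] * wh[js[1], js[2]])^(1 / 3) /
      (2 * (2 - 1))
    expect_equal(unname(got[i]), expected)
  }
  # fuzz: every weighted C equals the exhaustive triple sum
  for (s in 1:3) {
    set.seed(s)
    a <- matrix(runif(36), 6); a <- (a + t(a)) / 2; diag(a) <- 0
    a[a < 0.4] <- 0
    wh <- a / max(a)
    k <- rowSums(a > 0)
    oracle <- sapply(1:6, function(i) {
      if (k[i] < 2) return(0)
      acc <- 0
      for (j in 1:6) for (h in 1:6) {
        if (j != i && h != i && j != h) {
          acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
        }
      }
      acc / (k[i] * (k[i] - 1))
    })
    expect_equal(unname(clustering_coef(wt_graph(a))$per_node), oracle,
                 tolerance = 1e-12)
  }
})

test_that("characteristic path length matches hand values and Floyd-Warshall", {
  chain <- matrix(0, 3, 3); chain[1, 2] <- 1; chain[2, 3] <- 1
  chain <- chain + t(chain)
  expect_equal(char_path_length(bin_graph(chain))$L, 4 / 3)
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(char_path_length(bin_graph(k4))$L, 1)
  wchain <- matrix(0, 3, 3); wchain[1, 2] <- 0.5; wchain[2, 3] <- 0.5
  wchain <- wchain + t(wchain)
  expect_equal(char_path_length(wt_graph(wchain))$L, 8 / 3)
  # oracle on a random weighted graph
  set.seed(4)
  a <- matrix(runif(64), 8); a <- (a + t(a)) / 2; diag(a) <- 0
  a[a < 0.45] <- 0
  lens <- ifelse(a > 0, 1 / a, 0)
  d <- floyd_warshall(lens)
  ut <- d[upper.tri(d)]
  expect_equal(char_path_length(wt_graph(a))$L, mean(ut[is.finite(ut)]))
  # disconnected pairs are excluded with a message; empty graphs error
  two <- matrix(0, 4, 4); two[1, 2] <- 1; two[3, 4] <- 1; two <- two + t(two)
  expect_message(res <- char_path_length(bin_graph(two)), "disconnected")
  expect_equal(res$L, 1)
  expect_equal(res$n_disconnected_pairs, 4)
  expect_error(suppressMessages(char_path_length(bin_graph(matrix(0, 3, 3)))),
               "disconnected")
})

test_that("modularity matches an exhaustive partition search on 6 nodes", {
  two_tri <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    two_tri[e[1], e[2]] <- 1
  }
  two_tri <- two_tri + t(two_tri)
  got <- graph_modularity(bin_graph(two_tri), seed = 1)
  best <- max(vapply(all_partitions(6), function(p) newman_q(two_tri, p), 0))
  expect_equal(got$Q, 0.5)
  expect_equal(got$Q, best)
  expect_equal(length(unique(got$membership[1:3])), 1)
  expect_equal(length(unique(got$membership[4:6])), 1)
  expect_false(got$membership[1] == got$membership[4])
  # complete graph: no community structure, Q = 0
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(graph_modularity(bin_graph(k5), seed = 1)$Q, 0)
  # returned Q is internally consistent with its own partition
  set.seed(9)
  a <- matrix(rbinom(100, 1, 0.3), 10); a <- ((a + t(a)) > 0) + 0; diag(a) <- 0
  gm <- graph_modularity(bin_graph(a), seed = 2)
  expect_equal(gm$Q, newman_q(a, gm$membership), tolerance = 1e-12)
  expect_gte(gm$Q, newman_q(a, rep(1, 10)))
  expect_error(graph_modularity(bin_graph(matrix(0, 4, 4))), "no edges")
})

test_that("surrogate normalization is seeded and calibrated", {
  set.seed(2)
  er <- matrix(rbinom(30 * 30, 1, 0.3), 30)
  er <- ((er + t(er)) > 0) + 0; diag(er) <- 0
  g <- bin_graph(er)
  s1 <- surrogate_normalize(g, n_surrogates = 20, seed = 5)
  s2 <- surrogate_normalize(g, n_surrogates = 20, seed = 5)
  expect_identical(s1, s2) # same seed, same ensemble
  expect_lt(abs(s1$NC - 1), 0.25) # random graph self-normalizes
  expect_lt(abs(s1$NL - 1), 0.15)
  ring <- as.matrix(igraph::as_adjacency_matrix(
    igraph::make_lattice(30, nei = 2, periodic = TRUE), sparse = FALSE))
  sr <- surrogate_normalize(bin_graph(ring), n_surrogates = 20, seed = 1)
  expect_gt(sr$NC, 2) # lattice clustering far above rewired ensemble
})

test_that("small-worldness is the N-C / N-L ratio and detects small worlds", {
  set.seed(3)
  ws <- igraph::sample_smallworld(1, 60, 5, 0.1)
  a <- as.matrix(igraph::as_adjacency_matrix(igraph::simplify(ws), sparse = FALSE))
  g <- bin_graph(a)
  sn <- surrogate_normalize(g, n_surrogates = 20, seed = 7)
  expect_equal(small_worldness(g, n_surrogates = 20, seed = 7), sn$NC / sn$NL)
  expect_gt(small_worldness(g, n_surrogates = 20, seed = 7), 1)
})

test_that("regional means aggregate node metrics by scalp region", {
  lay <- generate_layout(32, 1)
  expect_equal(unname(regional_means(rep(0.7, 32), lay)),
               rep(0.7, 4))
  onehot <- as.numeric(seq_len(32) == which(lay$region == "frontal")[1])
  rm <- regional_means(onehot, lay)
  expect_equal(unname(rm["frontal"]), 1 / sum(lay$region == "frontal"))
  expect_equal(unname(rm[c("lateral", "central", "posterior")]), rep(0, 3))
  vals <- rnorm(32)
  expect_equal(unname(regional_means(vals, lay)),
               as.numeric(tapply(vals, lay$region, mean)[
                 c("frontal", "lateral", "central", "posterior")]))
  bad <- lay; bad$region[1] <- "occipital"
  expect_error(regional_means(vals, bad), "region")
})

test_that("mean binary degree follows the closed form 2k/n at every PT level", {
  m <- rand_conn(16, seed = 8)
  sw <- pt_sweep(m, mode = "binary")
  for (p in c(1, 20, 40, 58)) {
    k <- round(attr(sw, "pt_levels")[p] / 100 * 16 * 15 / 2)
    expect_equal(node_degree(sw[[p]])$mean, 2 * k / 16)
  }
})

test_that("metrics are invariant under node relabelling", {
  set.seed(11)
  a <- matrix(runif(100), 10); a <- (a + t(a)) / 2; diag(a) <- 0
  a[a < 0.5] <- 0
  perm <- sample(10)
  ap <- a[perm, perm]
  expect_equal(sort(node_degree(wt_graph(a))$per_node),
               sort(node_degree(wt_graph(ap))$per_node), ignore_attr = TRUE)
  expect_equal(clustering_coef(wt_graph(a))$mean,
               clustering_coef(wt_graph(ap))$mean)
  expect_equal(char_path_length(wt_graph(a))$L,
               char_path_length(wt_graph(ap))$L)
})
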