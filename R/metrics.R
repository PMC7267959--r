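as_wnet_graph <- function(g) {
  if (inherits(g, "wnet_graph")) return(g)
  a <- as.matrix(g)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-9) {
    stop_invalid("adjacency must be a symmetric square matrix")
  }
  diag(a) <- 0
  mode <- if (all(a %in% c(0, 1))) "binary" else "weighted"
  structure(list(adjacency = a, mode = mode, pt_percent = NA_real_,
                 labels = rownames(a) %||% sprintf("E%03d", seq_len(nrow(a))),
                 band = NA_character_), class = "wnet_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

graph_to_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      weighted = if (g$mode == "weighted") TRUE else NULL,
                                      diag = FALSE)
}

#' Node degree / strength
#'
#' Binary graphs: number of edges incident to each node. Weighted graphs:
#' node strength, the sum of incident edge weights.
#'
#' @param g A `wnet_graph` (or symmetric adjacency matrix).
#' @return List with `per_node` (named vector) and `mean`.
#' @export
node_degree <- function(g) {
  g <- as_wnet_graph(g)
  a <- g$adjacency
  if (g$mode == "binary") a <- (a > 0) + 0
  k <- rowSums(a)
  names(k) <- g$labels
  list(per_node = k, mean = mean(k))
}

#' Clustering coefficient
#'
#' Binary graphs: per node, the fraction of realized links among its
#' neighbours, `t_i / (k_i (k_i - 1) / 2)`, 0 when fewer than 2 neighbours.
#' Weighted graphs: the geometric-mean triangle intensity
#' `C_i = sum_{jh} (w_ij w_ih w_jh)^{1/3} / (k_i (k_i - 1))` on
#' max-normalized weights, the standard weighted generalization whose value
#' collapses to the binary one when all surviving weights equal 1.
#'
#' @param g A `wnet_graph`.
#' @return List with `per_node` and `mean`.
#' @export
clustering_coef <- function(g) {
  g <- as_wnet_graph(g)
  a <- g$adjacency
  bin <- (a > 0) + 0
  k <- rowSums(bin)
  denom <- k * (k - 1)
  if (g$mode == "binary") {
    tri <- diag(bin %*% bin %*% bin)   # 2 x number of triangles per node
    c_i <- ifelse(denom > 0, tri / denom, 0)
  } else {
    mx <- max(a)
    w3 <- (if (mx > 0) a / mx else a)^(1 / 3)
    tri <- diag(w3 %*% w3 %*% w3)
    c_i <- ifelse(denom > 0, tri / denom, 0)
  }
  names(c_i) <- g$labels
  list(per_node = c_i, mean = mean(c_i))
}

#' Characteristic path length
#'
#' Average shortest-path distance over all connected node pairs. Binary
#' graphs use hop counts; weighted graphs use edge lengths `1 / w`, the
#' usual mapping for connectivity-as-proximity weights. Pairs in different
#' components are excluded from the average and their count reported.
#'
#' @param g A `wnet_graph`.
#' @return List with `L` (mean), `n_disconnected_pairs`, `n_pairs_used`.
#' @export
char_path_length <- function(g) {
  g <- as_wnet_graph(g)
  ig <- graph_to_igraph(g)
  wts <- if (g$mode == "weighted") {
    1 / igraph::E(ig)$weight
  } else NA  # NA = unweighted hop count in igraph
  d <- igraph::distances(ig, weights = wts)
  ut <- d[upper.tri(d)]
  disc <- sum(!is.finite(ut))
  fin <- ut[is.finite(ut)]
  if (length(fin) == 0) stop_invalid("degenerate input: fully disconnected graph")
  if (disc > 0) {
    message(disc, " disconnected pair(s) excluded from the path-length average")
  }
  list(L = mean(fin), n_disconnected_pairs = disc, n_pairs_used = length(fin))
}

#' Modularity by seeded multi-restart Louvain optimization
#'
#' Greedy Louvain optimization of Newman modularity on the (weighted)
#' adjacency at resolution 1, run `restarts` times under seeded node-order
#' shuffles, keeping the best-Q partition. The returned Q is never below
#' the trivial single-module partition's 0.
#'
#' @param g A `wnet_graph` with at least one edge.
#' @param seed Integer seed.
#' @param restarts Number of restarts (default 10).
#' @return List with `Q` and `membership` (named integer vector).
#' @export
graph_modularity <- function(g, seed = 1, restarts = 10) {
  g <- as_wnet_graph(g)
  if (all(g$adjacency == 0)) stop_invalid("degenerate input: graph has no edges")
  ig <- graph_to_igraph(g)
  wts <- if (g$mode == "weighted") igraph::E(ig)$weight else NULL
  best_q <- -Inf
  best_m <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      perm <- sample(igraph::vcount(ig))
      igp <- igraph::permute(ig, perm)
      cl <- igraph::cluster_louvain(igp, weights = if (is.null(wts)) NULL else
        igraph::E(igp)$weight)
      q <- igraph::modularity(igp, igraph::membership(cl),
                              weights = if (is.null(wts)) NULL else igraph::E(igp)$weight)
      if (q > best_q) {
        best_q <- q
        # original vertex i sits at position perm[i] in the permuted graph
        best_m <- as.integer(igraph::membership(cl))[perm]
      }
    }
  })
  if (best_q < 0) {  # never worse than the trivial one-module partition
    best_q <- 0
    best_m <- rep(1L, nrow(g$adjacency))
  }
  names(best_m) <- g$labels
  list(Q = best_q, membership = best_m)
}

# Newman modularity of an explicit partition (used for cross-checks).
modularity_of <- function(adj, membership) {
  w <- sum(adj) / 2
  if (w == 0) return(0)
  k <- rowSums(adj)
  q <- 0
  for (cm in unique(membership)) {
    idx <- membership == cm
    q <- q + sum(adj[idx, idx]) / (2 * w) - (sum(k[idx]) / (2 * w))^2
  }
  q
}

#' Surrogate-normalized clustering and path length
#'
#' Divides the graph's mean clustering coefficient and characteristic path
#' length by their averages over an ensemble of random surrogates that
#' preserve the degree sequence (edge rewiring); for weighted graphs the
#' surviving weights are additionally shuffled over the rewired topology.
#' If rewiring fails on a degenerate graph, weight-shuffle-only surrogates
#' are used with a warning.
#'
#' @param g A `wnet_graph`.
#' @param n_surrogates Ensemble size (default 50).
#' @param seed Integer seed (same seed, same ensemble).
#' @return List with `NC`, `NL`, `C`, `L`, `C_surr`, `L_surr`.
#' @export
surrogate_normalize <- function(g, n_surrogates = 50, seed = 1) {
  g <- as_wnet_graph(g)
  if (n_surrogates < 1) stop_invalid("n_surrogates must be >= 1")
  C <- clustering_coef(g)$mean
  L <- suppressMessages(char_path_length(g)$L)
  ig <- graph_to_igraph(g)
  wts <- if (g$mode == "weighted") igraph::E(ig)$weight else NULL
  n_edges <- igraph::ecount(ig)
  cs <- ls <- numeric(n_surrogates)
  with_seed(seed, {
    for (s in seq_len(n_surrogates)) {
      igs <- tryCatch(
        igraph::rewire(ig, igraph::keeping_degseq(niter = max(10 * n_edges, 100))),
        error = function(e) NULL)
      if (is.null(igs)) {
        warning("degree-preserving rewiring failed; using weight-shuffle-only surrogate")
        igs <- ig
      }
      adj_s <- as.matrix(igraph::as_adjacency_matrix(igs, sparse = FALSE))
      # drawn in both modes so binary/weighted share one RNG stream
      perm <- sample.int(n_edges)
      if (!is.null(wts)) {
        sh <- wts[perm]
        ut <- which(upper.tri(adj_s) & adj_s > 0, arr.ind = TRUE)
        adj_w <- matrix(0, nrow(adj_s), ncol(adj_s))
        adj_w[ut] <- sh[seq_len(nrow(ut))]
        adj_s <- adj_w + t(adj_w)
      }
      gs <- structure(list(adjacency = adj_s, mode = g$mode,
                           pt_percent = g$pt_percent, labels = g$labels,
                           band = g$band), class = "wnet_graph")
      cs[s] <- clustering_coef(gs)$mean
      ls[s] <- suppressMessages(char_path_length(gs)$L)
    }
  })
  list(NC = C / mean(cs), NL = L / mean(ls), C = C, L = L,
       C_surr = cs, L_surr = ls)
}

#' Small-worldness
#'
#' `sigma = N-C / N-L`, the ratio of surrogate-normalized clustering to
#' surrogate-normalized path length; values above 1 indicate small-world
#' topology (lattice-like local clustering with random-like path lengths).
#'
#' @inheritParams surrogate_normalize
#' @return Scalar sigma.
#' @export
small_worldness <- function(g, n_surrogates = 50, seed = 1) {
  sn <- surrogate_normalize(g, n_surrogates = n_surrogates, seed = seed)
  sn$NC / sn$NL
}

#' Regional means of a node-level metric
#'
#' @param values Named (or layout-ordered) numeric vector of node values.
#' @param layout A `wnet_layout` with a `region` column.
#' @return Named vector of per-region means over
#'   frontal/lateral/central/posterior.
#' @export
regional_means <- function(values, layout) {
  assert_layout(layout)
  if (length(values) != nrow(layout)) {
    stop_invalid("values must align with the layout (one value per channel)")
  }
  known <- c("frontal", "lateral", "central", "posterior")
  if (!all(layout$region %in% known)) {
    stop_invalid("unknown region tag(s): ",
                 paste(setdiff(unique(layout$region), known), collapse = ", "))
  }
  out <- vapply(known, function(r) {
    if (any(layout$region == r)) mean(values[layout$region == r]) else NA_real_
  }, 0)
  out
}

#' All global measures of one thresholded graph
#'
#' Convenience wrapper returning mean degree/strength (K), mean clustering
#' (C), characteristic path length (L), modularity (Q) and, optionally,
#' the surrogate-normalized N-C, N-L and small-worldness sigma.
#'
#' @param g A `wnet_graph`.
#' @param seed Seed for modularity restarts and surrogates.
#' @param n_surrogates Surrogate count; 0 skips normalized measures.
#' @return Named numeric vector.
#' @export
metric_set <- function(g, seed = 1, n_surrogates = 0) {
  g <- as_wnet_graph(g)
  out <- c(K = node_degree(g)$mean,
           C = clustering_coef(g)$mean,
           L = suppressMessages(char_path_length(g)$L),
           Q = graph_modularity(g, seed = seed)$Q)
  if (n_surrogates > 0) {
    sn <- surrogate_normalize(g, n_surrogates = n_surrogates, seed = seed)
    out <- c(out, NC = sn$NC, NL = sn$NL, sigma = sn$NC / sn$NL)
  }
  out
}
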