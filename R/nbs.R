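# Per-edge group statistics across subjects, vectorized over edges.
# values: matrix subjects x edges; groups: factor.
edge_stat_matrix <- function(values, groups, stat = c("F", "t_onetail")) {
  stat <- match.arg(stat)
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- nrow(values)
  if (stat == "F") {
    gm <- rowsum(values, groups) / as.vector(table(groups))
    grand <- colMeans(values)
    ssb <- colSums(as.vector(table(groups)) * sweep(gm, 2, grand)^2)
    ssw <- colSums((values - gm[as.integer(groups), , drop = FALSE])^2)
    dfb <- k - 1
    dfw <- n - k
    fstat <- (ssb / dfb) / (ssw / dfw)
    fstat[ssw == 0] <- 0
    fstat
  } else {
    if (k != 2) stop_invalid("t_onetail requires exactly 2 groups")
    a <- values[groups == levels(groups)[1], , drop = FALSE]
    b <- values[groups == levels(groups)[2], , drop = FALSE]
    na <- nrow(a); nb <- nrow(b)
    sp2 <- ((na - 1) * apply(a, 2, var) + (nb - 1) * apply(b, 2, var)) /
      (na + nb - 2)
    tt <- (colMeans(a) - colMeans(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    tt[!is.finite(tt)] <- 0
    tt # one-tailed: only positive excursions cross a positive threshold
  }
}

#' Network-based statistic (NBS) permutation component test
#'
#' Computes a per-edge group statistic across subjects (one-way F for
#' multi-group designs, one-tailed pooled-variance t for two groups),
#' keeps edges whose statistic exceeds the component-forming threshold,
#' extracts connected components of the supra-threshold graph, and
#' controls the family-wise error rate over components by permuting group
#' labels and recording the null distribution of the maximum component
#' size (in edges). Component p-values use the add-observed convention
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param matrices List of per-subject `wnet_conn` (or symmetric matrices),
#'   all with the same channels.
#' @param groups Group label per subject.
#' @param stat `"F"` or `"t_onetail"`.
#' @param threshold Component-forming statistic threshold (e.g. 8 for F,
#'   3.8 for the post hoc t).
#' @param n_perm Number of label permutations (default 5000).
#' @param seed Integer seed.
#' @return A `wnet_nbs`: list with `components` (list of edge data frames),
#'   `component_p`, `max_size`, `threshold`, `n_perm`, `edge_stats`.
#' @export
nbs <- function(matrices, groups, stat = c("F", "t_onetail"),
                threshold, n_perm = 5000, seed = 1) {
  stat <- match.arg(stat)
  if (threshold <= 0) stop_invalid("threshold must be > 0")
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop_invalid("need >= 2 subjects per group")
  mats <- lapply(matrices, function(m) if (inherits(m, "wnet_conn")) m$wpli else as.matrix(m))
  labels <- rownames(mats[[1]]) %||% sprintf("E%03d", seq_len(nrow(mats[[1]])))
  n_ch <- nrow(mats[[1]])
  ut <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
  values <- t(vapply(mats, function(m) m[ut], numeric(nrow(ut))))

  obs_stats <- edge_stat_matrix(values, groups, stat)
  supra <- obs_stats > threshold
  if (mean(supra) > 0.5) {
    warning("more than half of all edges are supra-threshold; ",
            "the component-forming threshold is likely too lenient")
  }

  comp_of <- function(supra_mask) {
    if (!any(supra_mask)) return(list(sizes = integer(0), membership = NULL))
    adj <- matrix(0, n_ch, n_ch)
    e <- ut[supra_mask, , drop = FALSE]
    adj[e] <- 1
    adj[cbind(e[, 2], e[, 1])] <- 1
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cm <- igraph::components(ig)$membership
    comp_edge <- cm[e[, 1]]  # both endpoints share a component
    sizes <- as.integer(table(comp_edge))
    list(sizes = sizes, edge_comp = comp_edge, edges = e)
  }

  obs <- comp_of(supra)
  obs_max <- if (length(obs$sizes)) max(obs$sizes) else 0L

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      gp <- sample(groups)
      s <- edge_stat_matrix(values, gp, stat) > threshold
      if (!any(s)) return(0L)
      max(comp_of(s)$sizes)
    }, 0L)
  })

  components <- list()
  component_p <- numeric(0)
  if (length(obs$sizes)) {
    ids <- sort(unique(obs$edge_comp))
    ord <- order(-vapply(ids, function(id) sum(obs$edge_comp == id), 0L))
    for (id in ids[ord]) {
      e <- obs$edges[obs$edge_comp == id, , drop = FALSE]
      components[[length(components) + 1]] <- data.frame(
        from = labels[e[, 1]], to = labels[e[, 2]],
        statistic = obs_stats[supra][obs$edge_comp == id],
        stringsAsFactors = FALSE)
      component_p <- c(component_p,
                       (1 + sum(null_max >= nrow(e))) / (n_perm + 1))
    }
  }
  structure(list(components = components, component_p = component_p,
                 max_size = obs_max, threshold = threshold, n_perm = n_perm,
                 stat = stat, edge_stats = obs_stats, null_max = null_max,
                 labels = labels),
            class = "wnet_nbs")
}

#' @export
print.wnet_nbs <- function(x, ...) {
  cat(sprintf("<wnet_nbs> %s > %g: %d component(s), n_perm = %d\n",
              x$stat, x$threshold, length(x$components), x$n_perm))
  if (length(x$components)) {
    for (i in seq_along(x$components)) {
      cat(sprintf("  component %d: %d edges, p = %.4f\n", i,
                  nrow(x$components[[i]]), x$component_p[i]))
    }
  }
  invisible(x)
}
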