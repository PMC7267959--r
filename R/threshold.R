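#' Normalize a connectivity matrix by its maximum weight
#'
#' Divides every entry by the maximum off-diagonal value so the strongest
#' edge gets weight 1. This removes group-level differences in overall
#' connectivity strength before weighted graph measures are computed; the
#' rank order of edges is unchanged.
#'
#' @param m A `wnet_conn`.
#' @return A `wnet_conn` with maximum entry 1.
#' @export
normalize_weights <- function(m) {
  stopifnot(inherits(m, "wnet_conn"))
  mx <- max(m$wpli)
  if (mx <= 0) stop_invalid("degenerate input: all-zero connectivity matrix")
  m$wpli <- m$wpli / mx
  m
}

#' Proportional threshold of a connectivity matrix
#'
#' Retains the `pt_percent`% strongest edges: the `k = round(pt/100 *
#' n(n-1)/2)` largest upper-triangle weights survive, everything else is set
#' to 0, and the result is mirrored to keep symmetry. `mode = "weighted"`
#' keeps the surviving weights, `mode = "binary"` replaces them with 1.
#' Ties exactly at the cut are resolved deterministically in favour of the
#' lowest (row, column) index.
#'
#' @param m A `wnet_conn` (typically max-normalized for weighted use).
#' @param pt_percent Percentage of edges to retain, in `(0, 100]`.
#' @param mode `"weighted"` or `"binary"`.
#' @return A `wnet_graph` with fields `adjacency`, `mode`, `pt_percent`,
#'   `labels`, `band`.
#' @export
proportional_threshold <- function(m, pt_percent, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "wnet_conn"))
  if (!is.numeric(pt_percent) || pt_percent <= 0 || pt_percent > 100) {
    stop_invalid("pt_percent must lie in (0, 100]")
  }
  w <- m$wpli
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  n_edges <- nrow(ut)
  k <- round(pt_percent / 100 * n_edges)
  adj <- matrix(0, n, n, dimnames = dimnames(w))
  if (k > 0) {
    vals <- w[ut]
    ord <- order(-vals, ut[, 1], ut[, 2])  # ties: lowest (row, col) first
    keep <- ut[ord[seq_len(k)], , drop = FALSE]
    adj[keep] <- if (mode == "binary") 1 else vals[ord[seq_len(k)]]
    adj[cbind(keep[, 2], keep[, 1])] <- adj[keep]
  }
  structure(list(adjacency = adj, mode = mode, pt_percent = pt_percent,
                 labels = m$labels, band = m$band), class = "wnet_graph")
}

#' @export
print.wnet_graph <- function(x, ...) {
  cat(sprintf("<wnet_graph> %s, PT %g%%: %d nodes, %d edges\n",
              x$mode, x$pt_percent, nrow(x$adjacency),
              sum(x$adjacency[upper.tri(x$adjacency)] > 0)))
  invisible(x)
}

#' Sweep of proportional thresholds
#'
#' Applies [proportional_threshold()] over a grid of retention percentages,
#' by default 3 to 60% in steps of 1% (58 levels). Successive levels are
#' nested: the edge set at one level is contained in the next.
#'
#' @param m A `wnet_conn`.
#' @param pt_lo,pt_hi,step Grid of PT% levels.
#' @param mode `"weighted"` or `"binary"`.
#' @return Named list of `wnet_graph`, names `"pt<level>"`.
#' @export
pt_sweep <- function(m, pt_lo = 3, pt_hi = 60, step = 1,
                     mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  if (pt_lo > pt_hi) stop_invalid("pt_lo must be <= pt_hi")
  levels <- seq(pt_lo, pt_hi, by = step)
  out <- lapply(levels, function(p) proportional_threshold(m, p, mode))
  names(out) <- paste0("pt", levels)
  attr(out, "pt_levels") <- levels
  out
}

#' Mean connectivity strength
#'
#' Arithmetic mean of the upper-triangle entries of an (un-normalized)
#' connectivity matrix — the per-subject average WPLI used in group tests.
#'
#' @param m A `wnet_conn` or a symmetric matrix.
#' @return Scalar mean edge weight.
#' @export
mean_wpli <- function(m) {
  w <- if (inherits(m, "wnet_conn")) m$wpli else as.matrix(m)
  if (nrow(w) < 2) stop_invalid("need at least 2 channels")
  mean(w[upper.tri(w)])
}

#' Edge-distance ranges (mm) for the distance profile
#'
#' Four ranges of inter-electrode Euclidean distance: very short (< 57),
#' short (57--114), long (115--170), very long (171--227). Bins are
#' left-closed and right-open except the final one, which is closed.
#' @return Named list of `c(low, high)` in mm.
#' @export
distance_ranges <- function() {
  list(very_short = c(0, 57), short = c(57, 115), long = c(115, 171),
       very_long = c(171, 227))
}

#' Mean connectivity by edge length
#'
#' Bins every edge by the Euclidean distance between its electrodes into
#' the four [distance_ranges()] and averages the connectivity weight per
#' bin. Distances beyond 227 mm raise a warning and fall into the last bin.
#'
#' @param m A `wnet_conn`.
#' @param layout A `wnet_layout` matching the matrix labels.
#' @return A data frame with columns `range`, `low_mm`, `high_mm`,
#'   `n_edges`, `mean_wpli`.
#' @export
distance_profile <- function(m, layout) {
  stopifnot(inherits(m, "wnet_conn"))
  assert_layout(layout)
  if (!identical(as.character(layout$label), as.character(m$labels))) {
    stop_invalid("layout labels do not match connectivity matrix labels")
  }
  d <- layout_distances(layout)
  ut <- upper.tri(d)
  dd <- d[ut]
  ww <- m$wpli[ut]
  rng <- distance_ranges()
  breaks <- c(0, vapply(rng, `[`, 0, 2))
  if (any(dd > max(breaks))) {
    warning("edge distances beyond ", max(breaks),
            " mm assigned to the last range")
    dd <- pmin(dd, max(breaks))
  }
  bin <- cut(dd, breaks = breaks, right = FALSE, include.lowest = TRUE,
             labels = names(rng))
  bin[dd >= max(breaks)] <- "very_long"  # closed upper end of the final range
  data.frame(
    range = names(rng),
    low_mm = vapply(rng, `[`, 0, 1),
    high_mm = vapply(rng, `[`, 0, 2),
    n_edges = as.integer(table(bin)[names(rng)]),
    mean_wpli = vapply(names(rng), function(r) {
      if (any(bin == r, na.rm = TRUE)) mean(ww[bin == r]) else NA_real_
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
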