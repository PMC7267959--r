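#' Metric-versus-density curve over a threshold sweep
#'
#' Evaluates one network measure at every PT level of a [pt_sweep()]
#' result. The companion scalar `mean_over_levels` (the measure averaged
#' across thresholds) is the quantity entering group-level tests. Levels
#' at which the metric fails (e.g. a fully disconnected graph at very low
#' density) are dropped with a warning.
#'
#' @param sweep Output of [pt_sweep()].
#' @param metric One of `"K"`, `"C"`, `"L"`, `"Q"`, or a function
#'   `f(wnet_graph) -> scalar`.
#' @param seed Seed passed to seeded metrics (modularity).
#' @return A `wnet_curve`: list with `pt_levels`, `values`, `metric`,
#'   `mode`, `mean_over_levels`.
#' @export
metric_curve <- function(sweep, metric, seed = 1) {
  if (length(sweep) == 0) stop_invalid("empty threshold sweep")
  levels <- attr(sweep, "pt_levels") %||%
    vapply(sweep, function(g) g$pt_percent, 0)
  f <- if (is.function(metric)) {
    metric
  } else {
    switch(metric,
      K = function(g) node_degree(g)$mean,
      C = function(g) clustering_coef(g)$mean,
      L = function(g) suppressMessages(char_path_length(g)$L),
      Q = function(g) graph_modularity(g, seed = seed)$Q,
      stop_invalid("unknown metric '", metric, "'"))
  }
  vals <- rep(NA_real_, length(sweep))
  for (i in seq_along(sweep)) {
    vals[i] <- tryCatch(f(sweep[[i]]), error = function(e) {
      warning("metric failed at PT ", levels[i], "%: ", conditionMessage(e))
      NA_real_
    })
  }
  keep <- !is.na(vals)
  structure(list(
    pt_levels = levels[keep], values = vals[keep],
    metric = if (is.function(metric)) "custom" else metric,
    mode = sweep[[1]]$mode,
    mean_over_levels = mean(vals[keep])
  ), class = "wnet_curve")
}

#' Spearman density dependence with a permutation null
#'
#' Spearman rank correlation between metric values and PT levels, with a
#' bootstrap null built by permuting the values against the levels. The
#' dependence is flagged significant when the observed coefficient falls
#' outside the central 95% of the null (two-sided, 2.5% per tail).
#'
#' @param values Metric values (or a `wnet_curve`).
#' @param levels PT levels (ignored when `values` is a curve).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return List with `rho`, `null_quantiles` (2.5/50/97.5%), `significant`,
#'   `n_perm`, `degenerate`.
#' @export
density_dependence <- function(values, levels = NULL, n_perm = 5000, seed = 1) {
  if (inherits(values, "wnet_curve")) {
    levels <- values$pt_levels
    values <- values$values
  }
  if (length(values) < 3) stop_invalid("need at least 3 points")
  if (length(values) != length(levels)) stop_invalid("values/levels length mismatch")
  degenerate <- stats::sd(values) == 0
  rho <- if (degenerate) 0 else cor(values, levels, method = "spearman")
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      v <- sample(values)
      if (stats::sd(v) == 0) 0 else cor(v, levels, method = "spearman")
    }, 0)
  })
  qs <- quantile(null, c(0.025, 0.5, 0.975), names = FALSE)
  list(rho = rho,
       null_quantiles = c(q025 = qs[1], q50 = qs[2], q975 = qs[3]),
       significant = !degenerate && (rho < qs[1] | rho > qs[3]),
       n_perm = n_perm, degenerate = degenerate)
}

#' Fit a first-order power law to a metric-versus-density curve
#'
#' Models `value = scale * t^exponent + offset` with `t = PT% / 100` in
#' `(0, 1]`, by Levenberg-Marquardt nonlinear least squares with multiple
#' starts over an exponent grid to avoid local minima. 95% confidence
#' intervals come from the linearized covariance of the best fit.
#'
#' @param curve A `wnet_curve`, or numeric values via `values`/`pt_levels`.
#' @param values,pt_levels Used when `curve` is `NULL`.
#' @param exponent_grid Multi-start grid for the exponent.
#' @return A `wnet_powerlaw`: list with `scale`, `exponent`, `offset`,
#'   `sse`, `ci95` (3 x 2 matrix), `fitted`, `t`.
#' @export
fit_power_law <- function(curve = NULL, values = NULL, pt_levels = NULL,
                          exponent_grid = c(0.05, 0.25, 0.5, 1, 2)) {
  if (!is.null(curve)) {
    if (!inherits(curve, "wnet_curve")) stop_invalid("curve must be a wnet_curve")
    values <- curve$values
    pt_levels <- curve$pt_levels
  }
  if (length(values) < 4) stop_invalid("need at least 4 points to fit")
  t <- pt_levels / 100
  if (any(t <= 0 | t > 1)) stop_invalid("PT levels must map to t in (0, 1]")
  dat <- data.frame(t = t, y = values)
  best <- NULL
  best_sse <- Inf
  diags <- character(0)
  for (g0 in exponent_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * t^b + c, data = dat,
                        start = list(a = max(diff(range(values)), 0.1),
                                     b = g0, c = min(values)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        diags <<- c(diags, conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) {
      sse <- sum(stats::residuals(fit)^2)
      if (sse < best_sse) {
        best <- fit
        best_sse <- sse
      }
    }
  }
  if (is.null(best)) {
    stop_invalid("power-law fit failed for every start: ",
                 paste(unique(diags), collapse = "; "))
  }
  cf <- coef(best)
  se <- sqrt(diag(vcov(best)))
  crit <- qt(0.975, df = length(values) - 3)
  ci <- cbind(lower = cf - crit * se, upper = cf + crit * se)
  rownames(ci) <- c("scale", "exponent", "offset")
  structure(list(scale = unname(cf["a"]), exponent = unname(cf["b"]),
                 offset = unname(cf["c"]), sse = best_sse, ci95 = ci,
                 fitted = stats::fitted(best), t = t),
            class = "wnet_powerlaw")
}

#' @export
print.wnet_powerlaw <- function(x, ...) {
  cat(sprintf("<wnet_powerlaw> value = %.4f * t^%.4f + %.4f  (SSE %.3g)\n",
              x$scale, x$exponent, x$offset, x$sse))
  invisible(x)
}

#' Interval where the weighted curve's slope is below the binary one's
#'
#' Given power-law fits `C_b = f t^g + h` (binary) and `C_w = m t^n + q`
#' (weighted), solves the derivative-ratio condition
#' `dC_w/dC_b = (m n t^{n-1}) / (f g t^{g-1}) < 1` analytically on
#' `(0, 1]`. The ratio is `A t^{n-g}` with `A = m n / (f g)`, so the
#' boundary is `t* = A^{-1/(n-g)}` and the solution side follows the sign
#' of `n - g`. Returns the (possibly empty or full) sub-interval of
#' `(0, 1]` where weighted measures depend less on density than binary
#' ones.
#'
#' @param fit_binary,fit_weighted `wnet_powerlaw` fits (or lists with
#'   `scale` and `exponent`).
#' @return List with `lower`, `upper`, `lower_open`, `upper_open`, `empty`,
#'   `boundary` (the unclipped analytic boundary t*).
#' @export
derivative_ratio_condition <- function(fit_binary, fit_weighted) {
  f <- fit_binary$scale;  g <- fit_binary$exponent
  m <- fit_weighted$scale; n <- fit_weighted$exponent
  if (any(!is.finite(c(f, g, m, n)))) stop_invalid("non-finite fit coefficients")
  if (g == 0 || n == 0) stop_invalid("zero exponent: derivative ratio undefined")
  if (f * g <= 0 || m * n <= 0) {
    stop_invalid("scale/exponent products must be positive (increasing curves)")
  }
  A <- (m * n) / (f * g)
  d <- n - g
  empty_interval <- list(lower = NA_real_, upper = NA_real_,
                         lower_open = NA, upper_open = NA,
                         empty = TRUE, boundary = NA_real_)
  if (d == 0) {
    if (A < 1) {
      return(list(lower = 0, upper = 1, lower_open = TRUE, upper_open = FALSE,
                  empty = FALSE, boundary = NA_real_))
    }
    return(empty_interval)
  }
  tstar <- A^(-1 / d)
  if (d < 0) {
    # ratio decreasing in t: condition holds for t > t*
    if (tstar >= 1) return(empty_interval)
    list(lower = max(0, tstar), upper = 1, lower_open = TRUE,
         upper_open = FALSE, empty = FALSE, boundary = tstar)
  } else {
    # ratio increasing in t: condition holds for t < t*
    if (tstar <= 0) return(empty_interval)
    if (tstar > 1) {
      return(list(lower = 0, upper = 1, lower_open = TRUE, upper_open = FALSE,
                  empty = FALSE, boundary = tstar))
    }
    list(lower = 0, upper = min(1, tstar), lower_open = TRUE,
         upper_open = TRUE, empty = FALSE, boundary = tstar)
  }
}
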