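as_group_values <- function(values, groups) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values) %||% seq_along(values),
                  vapply(values, length, 0L))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_invalid("need at least 2 groups")
  tab <- table(groups)
  if (any(tab < 2)) {
    stop_invalid("every group needs >= 2 values; offending: ",
                 paste(names(tab)[tab < 2], collapse = ", "))
  }
  list(values = values, groups = groups)
}

#' Kruskal-Wallis omnibus group test
#'
#' Rank-based one-way test across groups with average-rank tie correction;
#' the H statistic is referred to a chi-square with `groups - 1` df.
#'
#' @param values Numeric vector, or a named list of per-group vectors.
#' @param groups Group labels aligned with `values` (ignored for a list).
#' @return A `wnet_stat` data frame row: `comparison`, `statistic`, `df`,
#'   `p_raw`, `p_adjusted`, `correction`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  gv <- as_group_values(values, groups)
  kt <- kruskal.test(gv$values, gv$groups)
  out <- data.frame(
    comparison = paste(levels(gv$groups), collapse = "|"),
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_raw = kt$p.value, p_adjusted = kt$p.value, correction = "none",
    stringsAsFactors = FALSE)
  class(out) <- c("wnet_stat", "data.frame")
  out
}

#' Pairwise Mann-Whitney tests with Holm-Bonferroni control
#'
#' Two-tailed Mann-Whitney U tests over all group pairs (or a supplied
#' subset), exact when both groups are small (<= 8) and untied, otherwise
#' normal approximation with tie and continuity correction; Holm step-down
#' adjustment over the comparison family.
#'
#' @inheritParams kruskal_wallis
#' @param comparisons Optional 2-column matrix of group-level pairs.
#' @param alpha Nominal level recorded in the output.
#' @return A `wnet_stat` data frame, one row per comparison.
#' @export
mann_whitney_posthoc <- function(values, groups = NULL, comparisons = NULL,
                                 alpha = 0.05) {
  gv <- as_group_values(values, groups)
  levs <- levels(gv$groups)
  if (is.null(comparisons)) comparisons <- t(combn(levs, 2))
  res <- lapply(seq_len(nrow(comparisons)), function(i) {
    a <- gv$values[gv$groups == comparisons[i, 1]]
    b <- gv$values[gv$groups == comparisons[i, 2]]
    exact <- length(a) <= 8 && length(b) <= 8 &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    data.frame(comparison = paste(comparisons[i, ], collapse = " vs "),
               statistic = unname(wt$statistic), df = NA_real_,
               p_raw = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_raw, method = "holm")
  out$correction <- "holm"
  out$significant <- out$p_adjusted < alpha
  class(out) <- c("wnet_stat", "data.frame")
  out
}

#' Mack-Skillings test for a group effect across blocks
#'
#' Rank-based test for a treatment (group) effect in a block design with
#' replication — the generalization of Friedman's test used here to ask
#' whether groups differ consistently across proportional-threshold
#' levels (blocks). Observations are ranked within each block; the
#' centred, variance-scaled group rank sums form a chi-square statistic
#' with `groups - 1` df.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation.
#' @param blocks Block label per observation (e.g. PT level).
#' @return A `wnet_stat` row with the chi-square statistic and p-value.
#' @export
mack_skillings <- function(values, groups, blocks) {
  groups <- factor(groups)
  blocks <- factor(blocks)
  k <- nlevels(groups)
  if (k < 2) stop_invalid("need at least 2 groups")
  cell <- table(groups, blocks)
  if (any(cell == 0)) {
    bad <- which(cell == 0, arr.ind = TRUE)[1, ]
    stop_invalid("empty group-block cell: group '", levels(groups)[bad[1]],
                 "', block '", levels(blocks)[bad[2]], "'")
  }
  # centred, scaled within-block rank sums per group
  t_i <- setNames(numeric(k), levels(groups))
  v_i <- setNames(numeric(k), levels(groups))
  for (b in levels(blocks)) {
    sel <- blocks == b
    r <- rank(values[sel], ties.method = "average")
    gb <- groups[sel]
    nj <- sum(sel)
    for (g in levels(groups)) {
      cij <- sum(gb == g)
      rij <- sum(r[gb == g])
      t_i[g] <- t_i[g] + (rij - cij * (nj + 1) / 2) / (nj + 1)
      v_i[g] <- v_i[g] + cij * (nj - cij) / (12 * (nj + 1))
    }
  }
  stat <- (k - 1) / k * sum(t_i^2 / v_i)
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  out <- data.frame(comparison = paste(levels(groups), collapse = "|"),
                    statistic = stat, df = k - 1, p_raw = p, p_adjusted = p,
                    correction = "none", stringsAsFactors = FALSE)
  class(out) <- c("wnet_stat", "data.frame")
  out
}

#' Group tests of connectivity per edge-distance range
#'
#' For each of the four distance ranges: a Kruskal-Wallis omnibus test
#' (Holm-adjusted over the 4 ranges) followed by pairwise Mann-Whitney
#' post hocs (Holm-adjusted over the pairs within each range).
#'
#' @param profiles Matrix or data frame of per-subject mean connectivity,
#'   one column per distance range (columns named as [distance_ranges()]).
#' @param groups Group label per subject (row).
#' @return List with `omnibus` (one row per range, Holm over ranges) and
#'   `posthoc` (rows per range x pair, Holm within range).
#' @export
distance_range_tests <- function(profiles, groups) {
  profiles <- as.data.frame(profiles)
  ranges <- names(distance_ranges())
  if (!all(ranges %in% names(profiles))) {
    stop_invalid("profiles must have columns ", paste(ranges, collapse = ", "))
  }
  omni <- do.call(rbind, lapply(ranges, function(r) {
    row <- kruskal_wallis(profiles[[r]], groups)
    row$range <- r
    row
  }))
  omni$p_adjusted <- p.adjust(omni$p_raw, method = "holm")
  omni$correction <- "holm"
  post <- do.call(rbind, lapply(ranges, function(r) {
    ph <- mann_whitney_posthoc(profiles[[r]], groups)
    ph$range <- r
    ph
  }))
  list(omnibus = omni, posthoc = post)
}

#' Mixed-design ANOVA gate for regional group differences
#'
#' Two-way mixed ANOVA with scalp region as the within-subject factor and
#' group as the between-subject factor (classical sums of squares,
#' sphericity assumed). Only when the region-by-group interaction is
#' significant at `alpha` are the per-region Kruskal-Wallis and pairwise
#' Mann-Whitney tests run (Holm over regions and over pairs respectively).
#'
#' @param data Data frame with columns `subject`, `group`, `region`,
#'   `value` — one row per subject x region.
#' @param alpha Gate level (default 0.05).
#' @return List with `interaction_F`, `interaction_p`, `gate_passed`, and
#'   (when passed) `omnibus` and `posthoc` tables.
#' @export
region_group_gate <- function(data, alpha = 0.05) {
  need <- c("subject", "group", "region", "value")
  if (!all(need %in% names(data))) {
    stop_invalid("data must have columns ", paste(need, collapse = ", "))
  }
  tab <- table(data$subject, data$region)
  if (any(tab != 1)) stop_invalid("need exactly one value per subject x region")
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$region <- factor(data$region)
  fit <- aov(value ~ group * region + Error(subject / region), data = data)
  within <- summary(fit)[["Error: subject:region"]][[1]]
  ix <- grep("group:region", rownames(within))
  Fv <- within[ix, "F value"]
  p <- within[ix, "Pr(>F)"]
  out <- list(interaction_F = Fv, interaction_p = p, gate_passed = p < alpha)
  if (out$gate_passed) {
    regions <- levels(data$region)
    omni <- do.call(rbind, lapply(regions, function(r) {
      sub <- data[data$region == r, ]
      row <- kruskal_wallis(sub$value, sub$group)
      row$region <- r
      row
    }))
    omni$p_adjusted <- p.adjust(omni$p_raw, method = "holm")
    omni$correction <- "holm"
    post <- do.call(rbind, lapply(regions, function(r) {
      sub <- data[data$region == r, ]
      ph <- mann_whitney_posthoc(sub$value, sub$group)
      ph$region <- r
      ph
    }))
    out$omnibus <- omni
    out$posthoc <- post
  }
  out
}

#' Spearman correlations between network measures and clinical scores
#'
#' Per group, band and measure, rank-correlates the per-subject measure
#' with each clinical score. P-values are reported uncorrected (and
#' flagged so); correlations with fewer than 5 paired observations are
#' flagged unstable.
#'
#' @param measures Long data frame: `subject`, `group`, `band`, `measure`,
#'   `value`.
#' @param clinical Data frame: `subject`, `group`, plus one column per score.
#' @return Data frame grid with `group`, `band`, `measure`, `score`, `rho`,
#'   `p_raw`, `n`, `correction` (`"uncorrected"`), `unstable`.
#' @export
clinical_correlations <- function(measures, clinical) {
  need_m <- c("subject", "group", "band", "measure", "value")
  if (!all(need_m %in% names(measures))) {
    stop_invalid("measures must have columns ", paste(need_m, collapse = ", "))
  }
  scores <- setdiff(names(clinical), c("subject", "group"))
  combos <- unique(measures[, c("group", "band", "measure")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- measures$group == combos$group[i] &
      measures$band == combos$band[i] &
      measures$measure == combos$measure[i]
    msub <- measures[sel, ]
    csub <- clinical[match(msub$subject, clinical$subject), ]
    for (sc in scores) {
      ok <- is.finite(msub$value) & is.finite(csub[[sc]])
      n <- sum(ok)
      if (n < 3) next
      ct <- suppressWarnings(
        cor.test(msub$value[ok], csub[[sc]][ok], method = "spearman"))
      rows[[length(rows) + 1]] <- data.frame(
        group = combos$group[i], band = combos$band[i],
        measure = combos$measure[i], score = sc,
        rho = unname(ct$estimate), p_raw = ct$p.value, n = n,
        correction = "uncorrected", unstable = n < 5,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
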