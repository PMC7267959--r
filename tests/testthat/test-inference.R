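test_that("Kruskal-Wallis matches the exhaustive rank computation", {
  res <- kruskal_wallis(list(a = c(1, 2, 3), b = c(101, 102, 103),
                             c = c(201, 202, 203)))
  # ranks are 1:3, 4:6, 7:9; H = 12/(9*10) * 3 * ((2-5)^2 + 0 + (8-5)^2)
  expect_equal(res$statistic, 12 / 90 * 3 * 18)
  expect_lt(res$p_raw, 0.05)
  # invariant under monotone transforms
  res2 <- kruskal_wallis(list(a = log(c(1, 2, 3)), b = log(c(101, 102, 103)),
                              c = log(c(201, 202, 203))))
  expect_equal(res2$statistic, res$statistic)
  expect_error(kruskal_wallis(list(a = 1, b = c(1, 2))), "2 values")
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  set.seed(7)
  ps <- replicate(500, {
    kruskal_wallis(list(a = rnorm(6), b = rnorm(6), c = rnorm(6)))$p_raw
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Mann-Whitney post hocs: family size, Holm oracle, exactness, symmetry", {
  set.seed(1)
  vals <- list(a = rnorm(5), b = rnorm(5) + 1, c = rnorm(5), d = rnorm(5) - 1)
  res <- mann_whitney_posthoc(vals)
  expect_equal(nrow(res), 6) # C(4,2)
  expect_equal(res$p_adjusted, holm_oracle(res$p_raw))
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_true(all(diff(sort(res$p_adjusted)) >= 0 |
                    abs(diff(sort(res$p_adjusted))) < 1e-15))
  # Holm <= Bonferroni, both >= raw
  expect_true(all(res$p_adjusted <= pmin(1, res$p_raw * 6) + 1e-15))
  # exact p equals the full-enumeration oracle for small untied samples
  a <- c(1.1, 2.3, 3.7); b <- c(0.4, 2.9, 4.2, 5.8)
  got <- mann_whitney_posthoc(c(a, b), rep(c("x", "y"), c(3, 4)))
  expect_equal(got$p_raw, mwu_exact_oracle(a, b))
  flipped <- mann_whitney_posthoc(c(b, a), rep(c("x", "y"), c(4, 3)))
  expect_equal(flipped$p_raw, got$p_raw)
})

test_that("Mack-Skillings behaves at the null, under shift, and under block offsets", {
  # all groups identical within every block -> statistic 0, p 1
  v <- rep(rep(1:5, each = 4), times = 3)
  g <- rep(rep(letters[1:4], 5), times = 3)
  b <- rep(1:3, each = 20)
  null_res <- mack_skillings(v, g, b)
  expect_equal(null_res$statistic, 0)
  expect_equal(null_res$p_raw, 1)
  # one group shifted in every block
  set.seed(2)
  k <- 4; blocks <- 10; reps <- 5
  g2 <- rep(rep(letters[1:k], each = reps), blocks)
  b2 <- rep(1:blocks, each = k * reps)
  v2 <- rnorm(length(g2)) + ifelse(g2 == "a", 10, 0)
  shift <- mack_skillings(v2, g2, b2)
  expect_lt(shift$p_raw, 0.05)
  # within-block permutation oracle agrees with the chi-square approximation
  v3 <- rnorm(length(g2)) + ifelse(g2 == "a", 0.55, 0)
  obs <- mack_skillings(v3, g2, b2)
  set.seed(3)
  perm_stats <- replicate(2000, {
    vp <- v3
    for (bl in unique(b2)) {
      sel <- b2 == bl
      vp[sel] <- vp[sel][sample(sum(sel))]
    }
    mack_skillings(vp, g2, b2)$statistic
  })
  p_perm <- mean(perm_stats >= obs$statistic)
  expect_lt(abs(p_perm - obs$p_raw), 0.05)
  # invariant to block-specific constants
  v4 <- v3 + rep(rnorm(blocks, 0, 50), each = k * reps)
  expect_equal(mack_skillings(v4, g2, b2)$statistic, obs$statistic)
  # dropping every observation of one group from one block empties a cell
  drop <- !(g2 == "a" & b2 == 1)
  expect_error(mack_skillings(v2[drop], g2[drop], b2[drop]), "cell")
})

test_that("distance-range tests have the right shape and localize planted effects", {
  set.seed(4)
  n <- 12
  mk <- function(shift_long) {
    data.frame(very_short = rnorm(n, 0.3, 0.02), short = rnorm(n, 0.25, 0.02),
               long = rnorm(n, 0.2, 0.02) + shift_long,
               very_long = rnorm(n, 0.15, 0.02) + shift_long)
  }
  prof <- rbind(mk(0), mk(-0.08))
  groups <- rep(c("HC", "AD"), each = n)
  res <- distance_range_tests(prof, groups)
  expect_equal(nrow(res$omnibus), 4)
  expect_equal(nrow(res$posthoc), 4) # 1 pair x 4 ranges here
  sig <- res$omnibus$range[res$omnibus$p_adjusted < 0.05]
  expect_setequal(sig, c("long", "very_long"))
  # with four groups the grid is 4 ranges x (1 omnibus + 6 post hocs)
  prof4 <- rbind(mk(0), mk(0), mk(0), mk(0))
  groups4 <- rep(c("HC", "AD", "DLB", "PDD"), each = n)
  res4 <- distance_range_tests(prof4, groups4)
  expect_equal(nrow(res4$omnibus), 4)
  expect_equal(nrow(res4$posthoc), 24)
})

test_that("identical groups rarely reject in the distance-range chain", {
  rejections <- 0
  for (s in 1:50) {
    set.seed(s + 500)
    prof <- data.frame(very_short = rnorm(16, 0.3, 0.03),
                       short = rnorm(16, 0.25, 0.03),
                       long = rnorm(16, 0.2, 0.03),
                       very_long = rnorm(16, 0.15, 0.03))
    res <- distance_range_tests(prof, rep(c("A", "B"), each = 8))
    gated <- res$omnibus$range[res$omnibus$p_adjusted < 0.05]
    hit <- any(res$posthoc$p_adjusted < 0.05 & res$posthoc$range %in% gated)
    rejections <- rejections + hit
  }
  expect_lte(rejections, 5) # <= 10% of 50 runs
})

test_that("the regional mixed-ANOVA gate matches a sums-of-squares oracle", {
  # 2 groups x 2 regions toy table, F computed from first principles
  df <- expand.grid(subject = sprintf("s%02d", 1:8), region = c("r1", "r2"))
  df$group <- rep(rep(c("g1", "g2"), each = 4), 2)
  set.seed(6)
  df$value <- rnorm(16) + ifelse(df$group == "g2" & df$region == "r2", 1.5, 0)
  res <- region_group_gate(df)
  # oracle: within-subject stratum decomposition
  cell <- with(df, tapply(value, list(group, region), mean))
  subj_mean <- with(df, tapply(value, subject, mean))
  grand <- mean(df$value)
  reg_mean <- with(df, tapply(value, region, mean))
  grp_mean <- with(df, tapply(value, group, mean))
  ss_int <- 4 * sum((cell - outer(grp_mean, reg_mean, `+`) + grand)^2)
  # within-subject residual after removing subject and region effects
  ss_err <- sum((df$value - subj_mean[df$subject] - reg_mean[df$region] + grand)^2) -
    ss_int
  f_oracle <- (ss_int / 1) / (ss_err / 6) # df_int = 1, df_err = (8-2)*(2-1)
  expect_equal(res$interaction_F, f_oracle, tolerance = 1e-8)
})

test_that("the regional gate opens only for region-specific group effects", {
  mk <- function(seed, posterior_shift, uniform_shift = 0) {
    set.seed(seed)
    df <- expand.grid(subject = sprintf("s%02d", 1:16),
                      region = c("frontal", "lateral", "central", "posterior"))
    df$group <- rep(rep(c("HC", "AD"), each = 8), 4)
    df$value <- rnorm(64, 1, 0.3) +
      ifelse(df$group == "AD", uniform_shift, 0) +
      ifelse(df$group == "AD" & df$region == "posterior", posterior_shift, 0)
    df
  }
  # group effect constant across regions: no interaction, no per-region tests
  res0 <- region_group_gate(mk(1, 0, uniform_shift = 1))
  expect_false(res0$gate_passed)
  expect_null(res0$omnibus)
  # posterior-only effect: interaction flagged in the majority of seeds
  hits <- sapply(1:20, function(s) {
    r <- region_group_gate(mk(s, posterior_shift = -1))
    r$gate_passed &&
      r$omnibus$p_adjusted[r$omnibus$region == "posterior"] < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("clinical correlations report the Spearman grid uncorrected", {
  meas <- data.frame(subject = sprintf("s%02d", 1:10), group = "DLB",
                     band = "alpha", measure = "mean_wpli",
                     value = seq(0.1, 1, 0.1))
  clin <- data.frame(subject = meas$subject, group = "DLB",
                     NPI = meas$value, MMSE = rnorm(10))
  res <- clinical_correlations(meas, clin)
  expect_equal(res$rho[res$score == "NPI"], 1)
  expect_equal(res$correction, rep("uncorrected", 2))
  expect_equal(res$rho[res$score == "MMSE"],
               spearman_oracle(meas$value, clin$MMSE))
  small <- clinical_correlations(meas[1:4, ], clin[1:4, ])
  expect_true(all(small$unstable))
})

test_that("NBS extracts components and controls the null", {
  set.seed(8)
  base <- lapply(1:12, function(i) {
    m <- matrix(runif(64, 0.19, 0.21), 8); m <- (m + t(m)) / 2; diag(m) <- 0
    m
  })
  groups <- rep(c("A", "B"), each = 6)
  # one planted edge, far above any noise edge's F
  mats <- base
  for (i in 1:6) mats[[i]][1, 2] <- mats[[i]][2, 1] <- mats[[i]][1, 2] + 0.5
  res <- nbs(mats, groups, stat = "F", threshold = 50, n_perm = 200, seed = 1)
  expect_equal(length(res$components), 1)
  expect_equal(nrow(res$components[[1]]), 1)
  expect_true(all(res$component_p >= 1 / 201 & res$component_p <= 1))
  # no group difference and a high threshold: no components
  res0 <- nbs(base, groups, stat = "F", threshold = 50, n_perm = 100, seed = 1)
  expect_equal(length(res0$components), 0)
  # lenient threshold warns
  expect_warning(nbs(mats, groups, stat = "F", threshold = 1e-4,
                     n_perm = 50, seed = 1), "lenient")
  # two-group one-tailed t statistic is available
  rest <- nbs(mats, groups, stat = "t_onetail", threshold = 3.8,
              n_perm = 200, seed = 2)
  expect_true(any(vapply(rest$components,
                         function(cmp) any(cmp$from == "E001" & cmp$to == "E002"),
                         TRUE)))
})
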