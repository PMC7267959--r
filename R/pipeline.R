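#' Default demonstration configuration
#'
#' A small four-group cohort (HC-, AD-, DLB-, PDD-like) on a 32-channel
#' layout with alpha coupling attenuated in all dementia-like groups and
#' posterior-anterior beta coupling additionally attenuated in the
#' DLB-like group, mirroring the planted contrasts the statistics stages
#' are designed to detect.
#'
#' @param seed Master seed.
#' @param n_subjects Subjects per group.
#' @param n_channels Layout size.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1, n_subjects = 8, n_channels = 32) {
  if (n_channels < 16) {
    stop_invalid("default_config couples channels up to index 14; use n_channels >= 16")
  }
  list(
    seed = seed,
    layout = list(n_channels = n_channels),
    cohort = list(
      n_epochs = 6, fs = 128, duration = 2,
      base_specs = list(
        list(band = "alpha", edges = list(c(1, 2), c(3, 4), c(5, 6), c(7, 8)),
             strength = 0.8, phase_lag = pi / 2, noise_sd = 0.3),
        list(band = "beta", edges = list(c(9, 10), c(11, 12), c(13, 14)),
             strength = 0.7, phase_lag = pi / 3, noise_sd = 0.3)),
      groups = list(
        list(name = "HC", n_subjects = n_subjects,
             attenuation = list(theta = 1, alpha = 1, beta = 1),
             clinical_means = list(MMSE = 29), clinical_sds = list(MMSE = 1)),
        list(name = "AD", n_subjects = n_subjects,
             attenuation = list(theta = 1, alpha = 0.6, beta = 0.9),
             clinical_means = list(MMSE = 21), clinical_sds = list(MMSE = 3)),
        list(name = "DLB", n_subjects = n_subjects,
             attenuation = list(theta = 1, alpha = 0.6, beta = 0.5),
             clinical_means = list(MMSE = 21), clinical_sds = list(MMSE = 3),
             planted_rho = list(MMSE = -0.6)),
        list(name = "PDD", n_subjects = n_subjects,
             attenuation = list(theta = 1, alpha = 0.6, beta = 0.7),
             clinical_means = list(MMSE = 20), clinical_sds = list(MMSE = 3)))),
    bands = c("alpha", "beta"),
    pt = list(lo = 3, hi = 60, step = 1),
    modes = c("binary", "weighted"),
    metrics = c("K", "C", "L", "Q"),
    n_surrogates = 0,
    density = list(n_perm = 1000),
    stats = list(nbs_stat = "F", nbs_threshold = 8, n_perm = 500),
    classify = list(groups = c("DLB", "AD"), folds = 4, repeats = 3),
    write_epochs = FALSE
  )
}

config_groups <- function(cfg) {
  lapply(cfg$cohort$groups, function(g) {
    group_spec(g$name, g$n_subjects,
               attenuation = unlist(g$attenuation),
               clinical_means = g$clinical_means,
               clinical_sds = g$clinical_sds,
               planted_rho = if (!is.null(g$planted_rho)) unlist(g$planted_rho),
               subject_sd = g$subject_sd %||% 0.15)
  })
}

config_specs <- function(cfg) {
  lapply(cfg$cohort$base_specs, function(s) {
    edges <- do.call(rbind, lapply(s$edges, function(e) as.numeric(e)))
    coupling_spec(s$band, edges, strength = s$strength,
                  phase_lag = s$phase_lag, noise_sd = s$noise_sd)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, connectivity, threshold, metrics, density, stats
#' and classify from a single configuration, writing per-stage outputs and
#' a manifest (stage status, runtimes, config hash, seeds) to `out_dir`.
#' Re-running the same configuration reproduces identical numeric outputs.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   JSON file with the same structure.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
    # fill only missing top-level keys; nested structures are taken as given
    defaults <- default_config()
    for (key in setdiff(names(defaults), names(config))) {
      config[[key]] <- defaults[[key]]
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  seeds <- derive_seeds(config$seed, 7)
  stages <- c("simulate", "connectivity", "threshold", "metrics",
              "density", "stats", "classify")
  manifest <- data.frame(stage = stages, status = "pending",
                         seconds = NA_real_, stringsAsFactors = FALSE)
  res <- list()
  finish <- function(ok = TRUE) {
    jsonlite::write_json(
      list(config_hash = cfg_hash, seed = config$seed,
           package_version = as.character(utils::packageVersion("wnet")),
           stages = manifest),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e) {
      manifest[manifest$stage == name, "status"] <<- paste("failed:", conditionMessage(e))
      finish(FALSE)
      stop_invalid("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    manifest[manifest$stage == name, "status"] <<- "ok"
    manifest[manifest$stage == name, "seconds"] <<-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  # 1. simulate ---------------------------------------------------------
  res$cohort <- run_stage("simulate", function() {
    layout <- generate_layout(config$layout$n_channels, seed = seeds[1])
    cohort <- generate_cohort(config_groups(config), layout, config_specs(config),
                              seed = seeds[1], n_epochs = config$cohort$n_epochs,
                              fs = config$cohort$fs,
                              duration = config$cohort$duration)
    write_layout(layout, file.path(out_dir, "layout.tsv"))
    write.table(cohort$clinical, file.path(out_dir, "clinical.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    if (isTRUE(config$write_epochs)) {
      dir.create(file.path(out_dir, "epochs"), showWarnings = FALSE)
      for (sid in names(cohort$recordings)) {
        write_epochs(cohort$recordings[[sid]],
                     file.path(out_dir, "epochs", paste0(sid, ".txt")))
      }
    }
    cohort$layout <- layout
    cohort
  })
  layout <- res$cohort$layout
  clinical <- res$cohort$clinical

  # 2. connectivity -----------------------------------------------------
  res$matrices <- run_stage("connectivity", function() {
    bands <- eeg_bands()[config$bands]
    dir.create(file.path(out_dir, "matrices"), showWarnings = FALSE)
    mats <- lapply(res$cohort$recordings, function(rec) {
      bm <- band_matrices(rec, bands = bands)
      for (bn in names(bm)) {
        write_matrix(bm[[bn]], file.path(out_dir, "matrices",
                                         paste0(rec$subject_id, "_", bn, ".tsv")))
      }
      bm
    })
    mats
  })

  # 3. threshold --------------------------------------------------------
  res$sweeps <- run_stage("threshold", function() {
    lapply(res$matrices, function(bm) {
      lapply(bm, function(m) {
        mn <- normalize_weights(m)
        lapply(setNames(config$modes, config$modes), function(mode) {
          pt_sweep(mn, config$pt$lo, config$pt$hi, config$pt$step, mode = mode)
        })
      })
    })
  })

  # 4. metrics ----------------------------------------------------------
  res$metrics <- run_stage("metrics", function() {
    rows <- list()
    for (sid in names(res$sweeps)) {
      grp <- clinical$group[clinical$subject == sid]
      for (bn in names(res$sweeps[[sid]])) {
        for (mode in names(res$sweeps[[sid]][[bn]])) {
          sw <- res$sweeps[[sid]][[bn]][[mode]]
          for (met in config$metrics) {
            cur <- suppressWarnings(metric_curve(sw, met, seed = seeds[4]))
            rows[[length(rows) + 1]] <- data.frame(
              subject = sid, group = grp, band = bn, mode = mode, metric = met,
              pt = cur$pt_levels, value = cur$values, stringsAsFactors = FALSE)
          }
        }
      }
    }
    df <- do.call(rbind, rows)
    write.table(df, file.path(out_dir, "metrics.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    df
  })

  # 5. density ----------------------------------------------------------
  res$density <- run_stage("density", function() {
    df <- res$metrics
    out <- list()
    for (bn in unique(df$band)) {
      for (met in unique(df$metric)) {
        fits <- list()
        for (mode in unique(df$mode)) {
          sub <- df[df$band == bn & df$metric == met & df$mode == mode, ]
          curve <- stats::aggregate(value ~ pt, sub, mean)  # pooled mean curve
          dd <- density_dependence(curve$value, curve$pt,
                                   n_perm = config$density$n_perm, seed = seeds[5])
          fit <- tryCatch(fit_power_law(values = curve$value, pt_levels = curve$pt),
                          error = function(e) NULL)
          fits[[mode]] <- fit
          out[[paste(bn, met, mode, sep = "_")]] <- list(
            rho = dd$rho, significant = dd$significant,
            fit = if (!is.null(fit)) list(scale = fit$scale, exponent = fit$exponent,
                                          offset = fit$offset, sse = fit$sse))
        }
        if (!is.null(fits$binary) && !is.null(fits$weighted) &&
            fits$binary$exponent != 0 && fits$weighted$exponent != 0) {
          iv <- tryCatch(derivative_ratio_condition(fits$binary, fits$weighted),
                         error = function(e) NULL)
          if (!is.null(iv)) out[[paste(bn, met, "interval", sep = "_")]] <- iv
        }
      }
    }
    jsonlite::write_json(out, file.path(out_dir, "density.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
  })

  # 6. stats ------------------------------------------------------------
  res$stats <- run_stage("stats", function() {
    dir.create(file.path(out_dir, "stats"), showWarnings = FALSE)
    groups <- clinical$group[match(names(res$matrices), clinical$subject)]
    out <- list()
    for (bn in config$bands) {
      mw <- vapply(res$matrices, function(bm) mean_wpli(bm[[bn]]), 0)
      omni <- kruskal_wallis(mw, groups)
      post <- mann_whitney_posthoc(mw, groups)
      omni$band <- bn; post$band <- bn
      out$mean_wpli_omnibus <- rbind(out$mean_wpli_omnibus, omni)
      out$mean_wpli_posthoc <- rbind(out$mean_wpli_posthoc, post)
      nb <- nbs(lapply(res$matrices, function(bm) bm[[bn]]), groups,
                stat = config$stats$nbs_stat,
                threshold = config$stats$nbs_threshold,
                n_perm = config$stats$n_perm, seed = seeds[6])
      out$nbs[[bn]] <- list(
        n_components = length(nb$components),
        component_p = nb$component_p,
        components = lapply(nb$components, function(cmp) cmp[, c("from", "to")]))
      prof <- t(vapply(res$matrices, function(bm) {
        setNames(distance_profile(bm[[bn]], layout)$mean_wpli,
                 names(distance_ranges()))
      }, numeric(4)))
      drt <- distance_range_tests(as.data.frame(prof), groups)
      drt$omnibus$band <- bn
      out$distance_omnibus <- rbind(out$distance_omnibus, drt$omnibus)
    }
    meas <- do.call(rbind, lapply(config$bands, function(bn) {
      data.frame(subject = names(res$matrices),
                 group = groups, band = bn, measure = "mean_wpli",
                 value = vapply(res$matrices, function(bm) mean_wpli(bm[[bn]]), 0),
                 stringsAsFactors = FALSE)
    }))
    out$clinical <- clinical_correlations(meas, clinical)
    write.table(out$mean_wpli_omnibus, file.path(out_dir, "stats", "mean_wpli_omnibus.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    write.table(out$mean_wpli_posthoc, file.path(out_dir, "stats", "mean_wpli_posthoc.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    write.table(out$clinical, file.path(out_dir, "stats", "clinical_correlations.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$nbs, file.path(out_dir, "stats", "nbs.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
  })

  # 7. classify ---------------------------------------------------------
  res$classification <- run_stage("classify", function() {
    pair <- config$classify$groups
    df <- res$metrics
    keep <- df$group %in% pair & df$mode == "weighted"
    agg <- stats::aggregate(value ~ subject + group + band + metric,
                            df[keep, ], mean)
    agg$key <- paste(agg$band, agg$metric, sep = "_")
    wide <- stats::reshape(agg[, c("subject", "group", "key", "value")],
                           idvar = c("subject", "group"), timevar = "key",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    x <- wide[, setdiff(names(wide), c("subject", "group")), drop = FALSE]
    rep_cl <- rf_crossval(x, wide$group, folds = config$classify$folds,
                          repeats = config$classify$repeats, seed = seeds[7])
    jsonlite::write_json(
      list(metrics = rep_cl$metrics, auroc_pooled = rep_cl$auroc_pooled,
           optimal_point = as.list(rep_cl$optimal_point),
           importance = rep_cl$importance),
      file.path(out_dir, "classification.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    rep_cl
  })

  finish()
  res$manifest <- manifest
  invisible(res)
}
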