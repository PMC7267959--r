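#' Band-limited coupling specification
#'
#' Describes one band's oscillatory content for the signal generator: which
#' channel pairs share a carrier, how strongly, and at what phase lag. The
#' generator mixes, per channel, a shared sinusoidal carrier (amplitude =
#' coupling strength), an independent same-band oscillator (amplitude =
#' 1 - strength) and white noise. A nonzero lag is required for the
#' coupling to be visible to the weighted phase lag index, which discards
#' zero-lag (volume-conduction-like) relations by construction.
#'
#' @param band Band name (`"theta"`, `"alpha"`, `"beta"`) or `c(low, high)` Hz.
#' @param edges Two-column matrix (or vector of length 2) of channel indices
#'   to couple; may be `NULL` for a pure-noise band.
#' @param strength Coupling strength in `[0, 1]`, recycled across edges.
#' @param phase_lag Phase lag in radians, recycled across edges.
#' @param noise_sd Standard deviation of additive broadband Gaussian noise.
#' @return A `wnet_coupling` list.
#' @export
#' @examples
#' coupling_spec("alpha", rbind(c(1, 2)), strength = 0.8, phase_lag = pi / 2)
coupling_spec <- function(band, edges = NULL, strength = 0.8,
                          phase_lag = pi / 2, noise_sd = 0.2) {
  edges_hz <- band_edges(band)
  if (!is.null(edges)) {
    if (is.vector(edges)) edges <- matrix(edges, ncol = 2, byrow = TRUE)
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop_invalid("edges must have two columns")
    strength <- rep_len(strength, nrow(edges))
    phase_lag <- rep_len(phase_lag, nrow(edges))
  } else {
    edges <- matrix(numeric(0), ncol = 2)
    strength <- numeric(0)
    phase_lag <- numeric(0)
  }
  if (any(strength < 0 | strength > 1)) {
    stop_invalid("coupling strength must lie in [0, 1]")
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  structure(list(
    band = if (is.character(band)) band else paste0(edges_hz, collapse = "-"),
    edges_hz = edges_hz, edge_list = edges,
    strength = strength, phase_lag = phase_lag, noise_sd = noise_sd
  ), class = "wnet_coupling")
}

# Scale all coupling strengths of a spec by a factor, clamped to [0, 1].
scale_coupling <- function(spec, factor) {
  spec$strength <- pmin(1, pmax(0, spec$strength * factor))
  spec
}

#' Generate an epoched multichannel recording
#'
#' Simulates `n_epochs` epochs of `duration` seconds. Per epoch and band,
#' every coupled pair shares one sinusoidal carrier whose frequency is drawn
#' uniformly inside the band (frequency jitter across epochs) and whose
#' starting phase is random; the second channel of the pair receives the
#' carrier delayed by the pair's phase lag. Channels additionally carry an
#' independent oscillator in the same band with amplitude `1 - strength`
#' (so strength 1 means a pure shared carrier) and additive white noise.
#'
#' @param layout A `wnet_layout` defining channel count and labels.
#' @param specs List of [coupling_spec()] objects; bands must not overlap.
#' @param n_epochs Number of epochs (>= 1).
#' @param fs Sampling rate in Hz; must be at least 4x the highest band edge.
#' @param duration Epoch length in seconds (default 2).
#' @param seed Integer seed; recordings are bit-identical for equal seeds.
#' @param subject_id Subject identifier stored in the recording.
#' @return A `wnet_recording`: list with `epochs` (array epochs x channels x
#'   samples), `fs`, `labels`, `layout`, `subject_id`.
#' @export
generate_recording <- function(layout, specs, n_epochs = 20, fs = 256,
                               duration = 2, seed = 1, subject_id = "S001") {
  assert_layout(layout)
  if (n_epochs < 1) stop_invalid("n_epochs must be >= 1")
  if (inherits(specs, "wnet_coupling")) specs <- list(specs)
  hi <- if (length(specs)) max(vapply(specs, function(s) s$edges_hz[2], 0)) else 0
  if (length(specs) && fs < 4 * hi) {
    stop_invalid("fs = ", fs, " Hz too low; need at least 4x the highest band edge (",
                 4 * hi, " Hz)")
  }
  if (length(specs) > 1) {
    iv <- t(vapply(specs, function(s) s$edges_hz, numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      stop_invalid("coupling specs have overlapping frequency bands")
    }
  }
  n_ch <- nrow(layout)
  for (spec in specs) {
    if (nrow(spec$edge_list) && max(spec$edge_list) > n_ch) {
      stop_invalid("coupling edge references channel ", max(spec$edge_list),
                   " but the layout has only ", n_ch, " channels")
    }
  }
  ns <- round(duration * fs)
  tt <- (seq_len(ns) - 1) / fs

  with_seed(seed, {
    epochs <- array(0, dim = c(n_epochs, n_ch, ns))
    for (e in seq_len(n_epochs)) {
      sig <- matrix(0, ns, n_ch)
      for (spec in specs) {
        lo <- spec$edges_hz[1]; hib <- spec$edges_hz[2]
        # carrier amplitude available to the background oscillator
        bg_amp <- rep(1, n_ch)
        if (nrow(spec$edge_list)) {
          for (k in seq_len(nrow(spec$edge_list))) {
            i <- spec$edge_list[k, 1]; j <- spec$edge_list[k, 2]
            s <- spec$strength[k]; phi <- spec$phase_lag[k]
            f0 <- runif(1, lo, hib)
            th0 <- runif(1, 0, 2 * pi)
            sig[, i] <- sig[, i] + s * sin(2 * pi * f0 * tt + th0)
            sig[, j] <- sig[, j] + s * sin(2 * pi * f0 * tt + th0 - phi)
            bg_amp[i] <- min(bg_amp[i], 1 - s)
            bg_amp[j] <- min(bg_amp[j], 1 - s)
          }
        }
        f_bg <- runif(n_ch, lo, hib)
        th_bg <- runif(n_ch, 0, 2 * pi)
        sig <- sig + sweep(sin(outer(tt, 2 * pi * f_bg) +
                               matrix(th_bg, ns, n_ch, byrow = TRUE)),
                           2, bg_amp, `*`)
        if (spec$noise_sd > 0) {
          sig <- sig + matrix(rnorm(ns * n_ch, 0, spec$noise_sd), ns, n_ch)
        }
      }
      epochs[e, , ] <- t(sig)
    }
    structure(list(
      subject_id = subject_id, epochs = epochs, fs = fs,
      labels = layout$label, layout = layout
    ), class = "wnet_recording")
  })
}

#' @export
print.wnet_recording <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<wnet_recording> %s: %d epochs x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Group specification for cohort simulation
#'
#' @param name Group label (e.g. `"HC"`, `"AD"`, `"DLB"`, `"PDD"`).
#' @param n_subjects Number of subjects (>= 2).
#' @param attenuation Named per-band multiplicative factor in `[0, 1]`
#'   applied to every coupling strength of that band (1 = no attenuation).
#' @param clinical_means,clinical_sds Named vectors of per-score normal
#'   parameters for the clinical table.
#' @param planted_rho Optional named vector of target Spearman correlations
#'   between a clinical score and the subject's mean planted coupling.
#' @param subject_sd Log-normal sd of the per-subject coupling multiplier
#'   (biological between-subject variability).
#' @return A `wnet_group` list.
#' @export
group_spec <- function(name, n_subjects, attenuation = c(theta = 1, alpha = 1, beta = 1),
                       clinical_means = NULL, clinical_sds = NULL,
                       planted_rho = NULL, subject_sd = 0.15) {
  if (n_subjects < 2) stop_invalid("n_subjects must be >= 2")
  if (any(attenuation < 0 | attenuation > 1)) {
    stop_invalid("attenuation factors must lie in [0, 1]")
  }
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 attenuation = attenuation, clinical_means = clinical_means,
                 clinical_sds = clinical_sds, planted_rho = planted_rho,
                 subject_sd = subject_sd), class = "wnet_group")
}

#' Simulate a multi-group cohort with planted connectivity effects
#'
#' Each subject's coupling strengths are the base specification scaled by
#' the group's per-band attenuation and a subject-level log-normal
#' multiplier. Clinical scores are drawn per group; when a target rank
#' correlation is planted, the score is built by mixing the standardized
#' rank of the subject's mean planted coupling with independent noise in a
#' Gaussian-copula fashion, which approaches (not guarantees) the target.
#'
#' @param groups List of [group_spec()] objects (>= 2).
#' @param layout A `wnet_layout`.
#' @param base_specs List of [coupling_spec()] objects shared by all groups
#'   before attenuation.
#' @param seed Master integer seed; per-subject seeds are derived from it.
#' @param n_epochs,fs,duration Passed to [generate_recording()].
#' @return List with `recordings` (list of `wnet_recording`), `clinical`
#'   (data frame: subject, group, one column per score), and `coupling`
#'   (per-subject mean effective coupling strength).
#' @export
generate_cohort <- function(groups, layout, base_specs, seed = 1,
                            n_epochs = 20, fs = 256, duration = 2) {
  if (inherits(groups, "wnet_group")) groups <- list(groups)
  if (length(groups) < 2) stop_invalid("need at least 2 groups")
  if (inherits(base_specs, "wnet_coupling")) base_specs <- list(base_specs)
  n_total <- sum(vapply(groups, function(g) g$n_subjects, 0L))
  seeds <- derive_seeds(seed, n_total + length(groups))

  recordings <- list()
  rows <- list()
  coupling <- numeric(0)
  idx <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    subj_mult <- with_seed(seeds[n_total + gi],
                           exp(rnorm(g$n_subjects, 0, g$subject_sd)))
    group_strengths <- numeric(g$n_subjects)
    for (si in seq_len(g$n_subjects)) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", g$name, si)
      specs <- lapply(base_specs, function(sp) {
        att <- if (!is.null(names(g$attenuation)) && sp$band %in% names(g$attenuation)) {
          g$attenuation[[sp$band]]
        } else 1
        scale_coupling(sp, att * subj_mult[si])
      })
      recordings[[sid]] <- generate_recording(
        layout, specs, n_epochs = n_epochs, fs = fs, duration = duration,
        seed = seeds[idx], subject_id = sid)
      eff <- unlist(lapply(specs, function(sp) sp$strength))
      group_strengths[si] <- if (length(eff)) mean(eff) else 0
      rows[[sid]] <- data.frame(subject = sid, group = g$name,
                                stringsAsFactors = FALSE)
    }
    coupling <- c(coupling, setNames(group_strengths,
                                     sprintf("%s%02d", g$name, seq_len(g$n_subjects))))
  }

  clinical <- do.call(rbind, rows)
  rownames(clinical) <- NULL
  # clinical scores, group by group, with optional planted rank correlation
  score_names <- unique(unlist(lapply(groups, function(g) names(g$clinical_means))))
  for (sc in score_names) clinical[[sc]] <- NA_real_
  off <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    rows_g <- off + seq_len(g$n_subjects)
    off <- off + g$n_subjects
    if (is.null(g$clinical_means)) next
    with_seed(seeds[n_total + gi] + 1L, {
      for (sc in names(g$clinical_means)) {
        mu <- g$clinical_means[[sc]]
        sdv <- if (!is.null(g$clinical_sds)) g$clinical_sds[[sc]] else 1
        rho <- if (!is.null(g$planted_rho)) g$planted_rho[sc] else NA_real_
        if (!is.na(rho)) {
          zc <- scale(rank(coupling[rows_g], ties.method = "average"))[, 1]
          z <- rho * zc + sqrt(max(0, 1 - rho^2)) * rnorm(g$n_subjects)
          clinical[rows_g, sc] <- mu + sdv * z
        } else {
          clinical[rows_g, sc] <- rnorm(g$n_subjects, mu, sdv)
        }
      }
    })
  }
  list(recordings = recordings, clinical = clinical, coupling = coupling)
}
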