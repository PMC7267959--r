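#' Windowed-Fourier time-frequency decomposition of an epoched recording
#'
#' Computes complex Fourier coefficients on a 0.5 Hz frequency grid spanning
#' the requested band. The analysis window at frequency `f` is
#' `cycles(f) / f` seconds long, where the cycle count ramps linearly from 3
#' at the band's low edge to 10 at its high edge (clipped to the epoch
#' length), with a Hann taper. Windows tile each epoch with 50% overlap.
#' The resulting coefficient set (one complex value per epoch, window
#' position, frequency bin and channel) is the observation set over which
#' cross-spectra and the weighted phase lag index are averaged.
#'
#' @param recording A `wnet_recording`.
#' @param band Band name or `c(low, high)` Hz.
#' @param step Frequency-grid step in Hz (default 0.5).
#' @param cycles Length-2 vector: cycle counts at the band's low and high
#'   edges (default `c(3, 10)`).
#' @param overlap Fractional window overlap in `[0, 0.9]` (default 0.5).
#' @return A `wnet_cspec`: complex coefficient matrix (observations x
#'   channels) plus an index data frame (`epoch`, `window`, `freq`).
#' @export
tfr_windowed_fourier <- function(recording, band, step = 0.5,
                                 cycles = c(3, 10), overlap = 0.5) {
  if (!inherits(recording, "wnet_recording")) {
    stop_invalid("recording must be a wnet_recording")
  }
  edges <- band_edges(band)
  fs <- recording$fs
  if (edges[2] >= fs / 2) {
    stop_invalid("band upper edge ", edges[2], " Hz is not below Nyquist (",
                 fs / 2, " Hz)")
  }
  d <- dim(recording$epochs)
  n_epochs <- d[1]; n_ch <- d[2]; ns <- d[3]
  epoch_sec <- ns / fs
  freqs <- seq(edges[1], edges[2], by = step)
  if (cycles[1] / freqs[1] > epoch_sec + 1e-12) {
    stop_invalid("epoch of ", epoch_sec, " s cannot fit ", cycles[1],
                 " cycles at ", freqs[1], " Hz (needs ",
                 round(cycles[1] / freqs[1], 3), " s)")
  }

  coef_list <- list()
  index_list <- list()
  obs <- 0L
  for (f in freqs) {
    cyc <- if (edges[2] > edges[1]) {
      cycles[1] + (cycles[2] - cycles[1]) * (f - edges[1]) / (edges[2] - edges[1])
    } else cycles[1]
    win_n <- min(ns, max(4L, round(cyc / f * fs)))
    hop <- max(1L, round(win_n * (1 - overlap)))
    starts <- seq(1L, ns - win_n + 1L, by = hop)
    taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(win_n) / (win_n + 1)) # Hann
    tloc <- (seq_len(win_n) - 1) / fs
    basis <- taper * exp(-2i * pi * f * tloc) / sum(taper)
    for (e in seq_len(n_epochs)) {
      x <- t(recording$epochs[e, , , drop = TRUE])  # samples x channels
      if (n_ch == 1) x <- matrix(recording$epochs[e, 1, ], ncol = 1)
      for (w in seq_along(starts)) {
        seg <- x[starts[w]:(starts[w] + win_n - 1L), , drop = FALSE]
        obs <- obs + 1L
        coef_list[[obs]] <- as.vector(crossprod(seg, basis))
        index_list[[obs]] <- c(e, w, f)
      }
    }
  }
  coefs <- do.call(rbind, coef_list)
  index <- do.call(rbind, index_list)
  structure(list(
    coef = coefs,
    index = data.frame(epoch = index[, 1], window = index[, 2], freq = index[, 3]),
    band = if (is.character(band)) band else paste(edges, collapse = "-"),
    labels = recording$labels, fs = fs, n_epochs = n_epochs
  ), class = "wnet_cspec")
}

#' Cross-spectrum observations for one channel pair
#'
#' @param cs A `wnet_cspec`.
#' @param i,j Channel indices or labels.
#' @return Complex vector of per-observation cross-spectra `X = c_i * conj(c_j)`.
#' @export
cross_spectrum <- function(cs, i, j) {
  if (is.character(i)) i <- match(i, cs$labels)
  if (is.character(j)) j <- match(j, cs$labels)
  cs$coef[, i] * Conj(cs$coef[, j])
}

#' Weighted phase lag index of one observation set
#'
#' Evaluates `|E[I(X)]| / E[|I(X)]|]` for a vector of complex cross-spectrum
#' observations, the scalar form of the WPLI estimator. When every
#' imaginary part is (numerically) zero the index is defined as 0,
#' signalling lack of lagged connectivity.
#'
#' @param x Complex vector of cross-spectrum observations.
#' @param tol Denominator tolerance below which 0 is returned.
#' @return WPLI in `[0, 1]`.
#' @export
#' @examples
#' wpli_pair(c(1i, -1i, 1i))  # imaginary parts {+1, -1, +1} -> 1/3
wpli_pair <- function(x, tol = 1e-12) {
  if (length(x) == 0) stop_invalid("empty observation set")
  im <- Im(x)
  den <- mean(abs(im))
  if (!is.finite(den) || den < tol) return(0)
  abs(mean(im)) / den
}

#' WPLI connectivity matrix from a cross-spectrum set
#'
#' For every channel pair the estimator `|E[I(X)]| / E[|I(X)]|]` is
#' evaluated with the expectation taken jointly over epochs, window
#' positions and in-band frequency bins (the default), or per epoch first
#' and then averaged (`pool = "per_epoch"`), a sensitivity-analysis option.
#'
#' @param cs A `wnet_cspec` from [tfr_windowed_fourier()].
#' @param pool `"pooled"` (default) or `"per_epoch"`.
#' @param tol Zero-denominator tolerance; such pairs get WPLI 0.
#' @return A `wnet_conn` with a symmetric, zero-diagonal matrix in `[0, 1]`.
#' @export
wpli <- function(cs, pool = c("pooled", "per_epoch"), tol = 1e-12) {
  pool <- match.arg(pool)
  if (!inherits(cs, "wnet_cspec")) stop_invalid("cs must be a wnet_cspec")
  if (nrow(cs$coef) == 0) stop_invalid("empty observation set")

  if (pool == "pooled") {
    w <- wpli_core(cs$coef, tol)
  } else {
    eps <- unique(cs$index$epoch)
    acc <- 0
    for (e in eps) {
      acc <- acc + wpli_core(cs$coef[cs$index$epoch == e, , drop = FALSE], tol)
    }
    w <- acc / length(eps)
  }
  dimnames(w) <- list(cs$labels, cs$labels)
  connectivity_matrix(w, band = cs$band, labels = cs$labels,
                      n_epochs = cs$n_epochs)
}

# Pooled WPLI over the rows of a complex coefficient matrix (obs x channels).
# Im(c_i conj(c_j)) per observation k is  B[k,i] A[k,j] - A[k,i] B[k,j]
# with A = Re(coef), B = Im(coef); the numerator sums analytically to
# (t(B) A - t(A) B), the denominator accumulates per-observation magnitudes.
wpli_core <- function(coefs, tol = 1e-12) {
  a <- Re(coefs); b <- Im(coefs)
  num <- crossprod(b, a) - crossprod(a, b)
  n_ch <- ncol(coefs)
  den <- matrix(0, n_ch, n_ch)
  for (k in seq_len(nrow(coefs))) {
    den <- den + abs(tcrossprod(b[k, ], a[k, ]) - tcrossprod(a[k, ], b[k, ]))
  }
  n_obs <- nrow(coefs)
  w <- matrix(0, n_ch, n_ch)
  ok <- den / n_obs >= tol
  w[ok] <- abs(num[ok]) / den[ok]
  w <- (w + t(w)) / 2   # numerator/denominator are antisymmetric/symmetric
  diag(w) <- 0
  pmin(pmax(w, 0), 1)
}

#' Construct a connectivity matrix container
#'
#' @param mat Symmetric numeric matrix with entries in `[0, 1]`.
#' @param band Band tag.
#' @param labels Channel labels (defaults to matrix dimnames).
#' @param n_epochs Number of epochs the estimate pooled over.
#' @return A `wnet_conn`.
#' @export
connectivity_matrix <- function(mat, band = "band", labels = NULL, n_epochs = NA_integer_) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop_invalid("connectivity matrix must be square")
  if (max(abs(mat - t(mat))) > 1e-9) stop_invalid("connectivity matrix must be symmetric")
  if (is.null(labels)) labels <- rownames(mat)
  if (is.null(labels)) labels <- sprintf("E%03d", seq_len(nrow(mat)))
  dimnames(mat) <- list(labels, labels)
  diag(mat) <- 0
  structure(list(wpli = mat, band = band, labels = labels,
                 n_epochs_used = n_epochs), class = "wnet_conn")
}

#' @export
print.wnet_conn <- function(x, ...) {
  cat(sprintf("<wnet_conn> band %s: %d channels, mean WPLI %.4f\n",
              x$band, nrow(x$wpli), mean_wpli(x)))
  invisible(x)
}

#' Per-band WPLI matrices for a recording
#'
#' One matrix per frequency band; epochs enter the WPLI expectation jointly
#' (they are not averaged as per-epoch WPLI values).
#'
#' @param recording A `wnet_recording`.
#' @param bands Named list of band edges (default [eeg_bands()]).
#' @param pool Pooling order for the WPLI expectation, see [wpli()].
#' @param ... Passed to [tfr_windowed_fourier()].
#' @return Named list of `wnet_conn`, one per band.
#' @export
band_matrices <- function(recording, bands = eeg_bands(), pool = "pooled", ...) {
  out <- lapply(names(bands), function(bn) {
    cs <- tfr_windowed_fourier(recording, bands[[bn]], ...)
    cs$band <- bn
    wpli(cs, pool = pool)
  })
  names(out) <- names(bands)
  out
}
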