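#' Canonical EEG frequency bands
#'
#' Band edges used throughout the package: theta 4--7.5 Hz, alpha
#' 8--13.5 Hz, beta 14--20.5 Hz. Connectivity is estimated on a 0.5 Hz
#' frequency grid spanning each band inclusively.
#'
#' @return Named list of two-element numeric vectors `c(low, high)` in Hz.
#' @export
#' @examples
#' eeg_bands()$alpha
eeg_bands <- function() {
  list(theta = c(4, 7.5), alpha = c(8, 13.5), beta = c(14, 20.5))
}

band_edges <- function(band) {
  bands <- eeg_bands()
  if (is.character(band)) {
    if (!band %in% names(bands)) {
      stop_invalid("unknown band '", band, "'; expected one of ",
                   paste(names(bands), collapse = ", "))
    }
    return(bands[[band]])
  }
  if (is.numeric(band) && length(band) == 2 && band[1] < band[2]) {
    return(as.numeric(band))
  }
  stop_invalid("band must be a band name or c(low, high) in Hz")
}

band_freq_grid <- function(band, step = 0.5) {
  edges <- band_edges(band)
  seq(edges[1], edges[2], by = step)
}
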