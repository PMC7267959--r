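#' Generate a spherical-cap sensor layout
#'
#' Places `n_channels` electrodes on the upper cap of a head-sized sphere
#' (radius 100 mm) using a Fibonacci lattice with a small seeded jitter, and
#' assigns each channel to one of four scalp regions by its position:
#' anterior channels are `frontal`, posterior ones `posterior`, a left/right
#' temporal band is `lateral` and the midline band is `central`. All
#' pairwise electrode distances are bounded by the sphere diameter (200 mm),
#' inside the 227 mm ceiling of the edge-distance analysis.
#'
#' @param n_channels Number of electrodes (>= 8).
#' @param seed Integer seed; layouts are bit-identical for equal seeds.
#' @return A `wnet_layout` data frame with columns `label`, `x`, `y`, `z`
#'   (mm; +y anterior, +x right, +z up) and `region`.
#' @export
#' @examples
#' lay <- generate_layout(32, seed = 1)
#' table(lay$region)
generate_layout <- function(n_channels, seed = 1) {
  if (!is.numeric(n_channels) || n_channels < 8) {
    stop_invalid("n_channels must be >= 8")
  }
  n <- as.integer(n_channels)
  radius <- 100 # mm; diameter 200 mm keeps every pair within 227 mm

  with_seed(seed, {
    # Fibonacci lattice restricted to the upper cap z/R in [0.05, 0.95]
    golden <- (1 + sqrt(5)) / 2
    i <- seq_len(n) - 0.5
    zfrac <- 0.05 + 0.9 * i / n
    theta <- 2 * pi * i / golden
    jitter <- runif(n, -0.02, 0.02) # radians, keeps positions distinct per seed
    theta <- theta + jitter
    rho <- sqrt(pmax(0, 1 - zfrac^2))
    x <- radius * rho * cos(theta)
    y <- radius * rho * sin(theta)
    z <- radius * zfrac

    region <- ifelse(y >= 0.35 * radius, "frontal",
              ifelse(y <= -0.35 * radius, "posterior",
              ifelse(abs(x) >= 0.45 * radius, "lateral", "central")))

    layout <- data.frame(
      label = sprintf("E%03d", seq_len(n)),
      x = x, y = y, z = z,
      region = region,
      stringsAsFactors = FALSE
    )
    class(layout) <- c("wnet_layout", "data.frame")
    layout
  })
}

layout_positions <- function(layout) {
  as.matrix(layout[, c("x", "y", "z")])
}

#' Pairwise inter-electrode Euclidean distances
#'
#' @param layout A `wnet_layout`.
#' @return Symmetric matrix of distances in mm, labelled by channel.
#' @export
layout_distances <- function(layout) {
  d <- as.matrix(stats::dist(layout_positions(layout)))
  dimnames(d) <- list(layout$label, layout$label)
  d
}

assert_layout <- function(layout) {
  need <- c("label", "x", "y", "z", "region")
  if (!is.data.frame(layout) || !all(need %in% names(layout))) {
    stop_invalid("layout must have columns ", paste(need, collapse = ", "))
  }
  invisible(layout)
}

#' @export
print.wnet_layout <- function(x, ...) {
  cat(sprintf("<wnet_layout> %d channels; regions: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$region)),
                            as.integer(table(x$region))), collapse = " ")))
  invisible(x)
}
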