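#' Generate a synthetic rod radial profile
#'
#' Builds an idealized rotationally averaged intensity profile for a
#' cylindrical rod: a plateau of intensity out to `outer_radius` with a
#' logistic falling edge of width `falloff`, optionally decorated with two
#' Gaussian leaflet peaks (an engulfed membrane tube), plus seeded Gaussian
#' noise. The profile is normalized to a maximum of 1.
#'
#' @param outer_radius Rod outer radius in Angstrom, positive.
#' @param falloff Edge width in Angstrom; 0 gives an ideal step edge.
#' @param leaflet_peaks Optional pair of radii (Angstrom) at which leaflet
#'   peaks are placed; both must lie in `[0, outer_radius]`.
#' @param peak_sigma_A Gaussian width of the leaflet peaks.
#' @param noise_sigma Additive Gaussian noise standard deviation (on the
#'   unit-normalized scale).
#' @param dr Radial grid step in Angstrom.
#' @param r_max Extent of the radial grid; default reaches well past the
#'   edge.
#' @param seed Integer seed for the noise.
#'
#' @return A [as_radial_profile()] tibble.
#' @examples
#' generate_radial_profile(107.5, falloff = 4, seed = 1)
#' @export
generate_radial_profile <- function(outer_radius, falloff = 4,
                                    leaflet_peaks = NULL,
                                    peak_sigma_A = 3,
                                    noise_sigma = 0, dr = 1,
                                    r_max = NULL, seed = NULL) {
  check_number(outer_radius, "outer_radius")
  if (outer_radius <= 0) abort("`outer_radius` must be positive.")
  check_number(falloff, "falloff", lower = 0)
  if (is.null(r_max)) r_max <- outer_radius + max(30, 6 * falloff)
  r <- seq(0, r_max, by = dr)

  edge <- if (falloff <= 1e-9) {
    as.numeric(r < outer_radius)
  } else {
    stats::plogis((outer_radius - r) / falloff)
  }

  if (is.null(leaflet_peaks)) {
    v <- edge
  } else {
    if (length(leaflet_peaks) != 2 ||
        any(leaflet_peaks < 0 | leaflet_peaks > outer_radius)) {
      abort("`leaflet_peaks` must be two radii inside [0, outer_radius].")
    }
    v <- 0.55 * edge +
      0.45 * exp(-(r - leaflet_peaks[1])^2 / (2 * peak_sigma_A^2)) +
      0.45 * exp(-(r - leaflet_peaks[2])^2 / (2 * peak_sigma_A^2))
  }

  if (noise_sigma > 0) {
    v <- with_seed(seed, v + rnorm(length(v), 0, noise_sigma))
    v <- pmax(v, 0)
  }
  as_radial_profile(r, v)
}
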