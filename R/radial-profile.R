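#' Build a radial profile tibble
#'
#' A radial profile is the rotationally averaged intensity of a map or image
#' as a function of radius, normalized to a maximum of 1. Radii must start
#' at 0 and increase strictly.
#'
#' @param radius_A Radial grid in Angstrom, strictly increasing from 0.
#' @param intensity Intensities on that grid; finite.
#' @param normalize Divide by the maximum so that `max(intensity) == 1`
#'   (default `TRUE`).
#'
#' @return A tibble of class `radial_profile` with columns `radius_A` and
#'   `intensity`.
#' @export
as_radial_profile <- function(radius_A, intensity, normalize = TRUE) {
  if (length(radius_A) != length(intensity) || length(radius_A) < 2) {
    abort("`radius_A` and `intensity` must be equal-length vectors (>= 2).")
  }
  if (radius_A[1] < 0 || any(diff(radius_A) <= 0)) {
    abort("`radius_A` must be non-negative and strictly increasing.")
  }
  if (!all(is.finite(intensity))) abort("`intensity` must be finite.")
  if (normalize) {
    m <- max(intensity)
    if (m <= 0) abort("cannot normalize a profile with non-positive maximum.")
    intensity <- intensity / m
  }
  out <- tibble(radius_A = as.numeric(radius_A),
                intensity = as.numeric(intensity))
  class(out) <- c("radial_profile", class(out))
  out
}

#' Rotationally averaged radial intensity profile
#'
#' Averages intensities of a 2D image (matrix) or 3D map (array) in annular
#' bins of width `pixel_size` around `center`. For a 3D map the average is
#' taken over all slices along the long (helical) axis, i.e. cylindrically.
#'
#' @param x A numeric matrix (2D) or 3D array. For 3D input the third
#'   dimension is taken as the axial direction.
#' @param pixel_size Pixel size in Angstrom per pixel.
#' @param center Centre in pixel coordinates `c(row, col)` (1-based). Default
#'   is the geometric centre of the in-plane dimensions.
#'
#' @return A [as_radial_profile()] tibble, normalized to max 1.
#' @export
radial_profile <- function(x, pixel_size, center = NULL) {
  check_number(pixel_size, "pixel_size")
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  nd <- length(dim(x))
  if (!nd %in% c(2L, 3L)) abort("`x` must be a 2D matrix or 3D array.")
  d <- dim(x)[1:2]
  if (is.null(center)) center <- (d + 1) / 2
  if (length(center) != 2 || any(center < 1) || any(center > d)) {
    abort("`center` must be c(row, col) inside the image bounds.")
  }
  rr <- sqrt(outer((seq_len(d[1]) - center[1])^2,
                   (seq_len(d[2]) - center[2])^2, "+"))
  bin <- as.integer(round(rr))  # bins of one pixel width
  vals <- if (nd == 2L) x else apply(x, c(1, 2), mean)
  sums <- tapply(as.vector(vals), as.vector(bin), mean)
  radii <- as.numeric(names(sums)) * pixel_size
  ord <- order(radii)
  as_radial_profile(radii[ord], as.numeric(sums)[ord])
}

round_to_increment <- function(x, increment) {
  # round-half-up to the nearest multiple of `increment`
  floor(x / increment + 0.5) * increment
}

#' Rod diameter at an intensity cutoff
#'
#' Reads the radius at which the normalized radial profile falls through the
#' cutoff (outermost falling-edge crossing, linearly interpolated between
#' grid points), doubles it, and rounds to the nearest diameter increment
#' (half-up). When several profiles of the same symmetry class are supplied,
#' their cutoff radii are averaged before conversion. Reading the outermost
#' crossing means luminal density inside wide rods cannot shrink the
#' measured diameter.
#'
#' @param profile A [as_radial_profile()] tibble (normalized).
#' @param cutoff Intensity cutoff in (0, 1); default 0.3.
#' @param increment Rounding increment in Angstrom; default 5.
#' @param class_members Optional list of additional profiles belonging to the
#'   same class; their cutoff radii are averaged with `profile`'s.
#'
#' @return Diameter in Angstrom (a multiple of `increment`).
#' @examples
#' p <- as_radial_profile(0:150, ifelse(0:150 < 100, 1, 0))
#' diameter_at_cutoff(p)  # 200
#' @export
diameter_at_cutoff <- function(profile, cutoff = 0.3, increment = 5,
                               class_members = NULL) {
  check_number(cutoff, "cutoff")
  if (cutoff <= 0 || cutoff >= 1) abort("`cutoff` must be in (0, 1).")
  radii <- cutoff_radius(profile, cutoff)
  if (!is.null(class_members)) {
    radii <- c(radii, vapply(class_members, cutoff_radius, numeric(1),
                             cutoff = cutoff))
  }
  round_to_increment(2 * mean(radii), increment)
}

cutoff_radius <- function(profile, cutoff) {
  r <- profile$radius_A
  v <- profile$intensity
  if (max(v) <= cutoff) {
    abort(sprintf("profile never exceeds the cutoff %.2f.", cutoff))
  }
  above <- v >= cutoff
  # outermost falling edge: last index i with v[i] >= cutoff > v[i + 1]
  idx <- which(above[-length(v)] & !above[-1])
  if (length(idx) == 0) {
    # profile still above cutoff at the last grid point
    return(r[length(r)])
  }
  i <- max(idx)
  frac <- (v[i] - cutoff) / (v[i] - v[i + 1])
  r[i] + frac * (r[i + 1] - r[i])
}

#' Bilayer leaflet radii from a radial profile
#'
#' Finds the two highest local intensity maxima of a membrane-tube radial
#' profile (one per bilayer leaflet), refines each peak position with a
#' three-point parabola, and reports inner and outer leaflet radii plus
#' their separation.
#'
#' @param profile A [as_radial_profile()] tibble.
#' @param window Optional radial search window `c(min_A, max_A)`.
#'
#' @return A one-row tibble with columns `inner_A`, `outer_A`,
#'   `separation_A`.
#' @export
leaflet_radii <- function(profile, window = NULL) {
  r <- profile$radius_A
  v <- profile$intensity
  if (!is.null(window)) {
    keep <- r >= window[1] & r <= window[2]
    r <- r[keep]
    v <- v[keep]
  }
  n <- length(v)
  if (n < 3) abort("profile too short for peak finding.")
  i <- 2:(n - 1)
  is_max <- v[i] > v[i - 1] & v[i] >= v[i + 1]
  peaks <- i[is_max]
  if (length(peaks) < 2) {
    abort("fewer than two local maxima in the search window; cannot assign leaflet radii.")
  }
  top2 <- peaks[order(v[peaks], decreasing = TRUE)][1:2]
  refined <- sort(vapply(top2, function(j) parabolic_vertex(r, v, j),
                         numeric(1)))
  tibble(inner_A = refined[1], outer_A = refined[2],
         separation_A = diff(refined))
}

# three-point parabolic sub-grid refinement around index j
parabolic_vertex <- function(r, v, j) {
  y1 <- v[j - 1]; y2 <- v[j]; y3 <- v[j + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 0.5), -0.5)
  r[j] + delta * (r[j + 1] - r[j])
}
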