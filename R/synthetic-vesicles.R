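#' Generate a synthetic vesicle field with known ground truth
#'
#' Renders a grayscale cryo-image-like field of circular (optionally
#' perturbed) vesicles together with the corresponding binary membrane
#' segmentation and an exact ground-truth table. Each membrane appears as
#' two dark concentric rings (the two bilayer leaflets, intensity minima on
#' a zero-mean background) whose radial separation equals that vesicle's
#' bilayer spacing; the mask is the union of the membrane annuli, one closed
#' connected component per vesicle. A fraction of vesicles is nested inside
#' a larger parent vesicle at a controlled enclosure gap, emulating
#' double-membrane (intra-luminal-vesicle-like) topologies.
#'
#' Defaults reflect the segmentation scale and vesicle statistics of
#' PspA/liposome cryo-EM experiments: 7 Angstrom pixels, perimeters of
#' roughly 90-200 nm, bilayer spacings around 28-40 Angstrom and enclosure
#' gaps around 58-76 Angstrom.
#'
#' @param n_vesicles Number of vesicles (>= 0).
#' @param nested_fraction Fraction of vesicles given a parent, in [0, 1].
#'   `floor(n_vesicles * nested_fraction)` vesicles are nested.
#' @param pixel_size Pixel size in Angstrom per pixel (default 7).
#' @param image_size Side length in pixels, or `NULL` to size the field
#'   automatically for the requested vesicle count.
#' @param radius_range_px Range of vesicle mid-radii in pixels for top-level
#'   vesicles.
#' @param bilayer_spacing_A Range (or single value) of leaflet-to-leaflet
#'   spacings in Angstrom, sampled uniformly per vesicle.
#' @param enclosure_gap_A Range (or single value) of skeleton-to-skeleton
#'   enclosure gaps for nested vesicles, in Angstrom.
#' @param min_child_radius_px Smallest allowed nested-vesicle mid-radius.
#' @param contour_perturbation Relative amplitude (>= 0) of a low-order
#'   Fourier perturbation of the vesicle contour; 0 gives perfect circles.
#' @param noise_sigma Standard deviation of additive Gaussian background
#'   noise, in units of the membrane contrast depth (which is 1).
#' @param ring_sigma_px Gaussian radial width of each leaflet ring (pixels).
#' @param mask_halfwidth_px Extra mask half-width beyond the leaflet rings.
#' @param margin_px Clearance kept from the image border and between
#'   non-nested vesicles.
#' @param max_retries Placement retries before a placement-failure error.
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   field exactly.
#'
#' @return An object of class `synthetic_field`: a list with elements
#'   `intensity` (numeric matrix), `mask` (0/1 integer matrix),
#'   `pixel_size`, `truth` (tibble with one row per vesicle: centre, radius,
#'   spacing, exact perimeter in nm, parent link and exact enclosure
#'   distance in Angstrom) and `seed`.
#' @examples
#' f <- generate_vesicle_field(n_vesicles = 6, seed = 1, image_size = 420)
#' f$truth
#' @export
generate_vesicle_field <- function(n_vesicles = 50,
                                   nested_fraction = 0,
                                   pixel_size = 7,
                                   image_size = NULL,
                                   radius_range_px = c(20, 46),
                                   bilayer_spacing_A = c(28, 40),
                                   enclosure_gap_A = c(58, 76),
                                   min_child_radius_px = 10,
                                   contour_perturbation = 0,
                                   noise_sigma = 0,
                                   ring_sigma_px = 1,
                                   mask_halfwidth_px = 1,
                                   margin_px = 4,
                                   max_retries = 1000,
                                   seed = NULL) {
  if (n_vesicles < 0 || n_vesicles != round(n_vesicles)) {
    abort("`n_vesicles` must be a non-negative integer.")
  }
  check_number(nested_fraction, "nested_fraction", lower = 0, upper = 1)
  check_number(pixel_size, "pixel_size")
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  check_number(contour_perturbation, "contour_perturbation", lower = 0)
  bilayer_spacing_A <- rep(bilayer_spacing_A, length.out = 2)
  enclosure_gap_A <- rep(enclosure_gap_A, length.out = 2)
  radius_range_px <- rep(radius_range_px, length.out = 2)

  n_nested <- floor(n_vesicles * nested_fraction)
  n_top <- n_vesicles - n_nested

  if (is.null(image_size)) {
    # size the field so that outer annuli cover ~30% of the area
    outer <- mean(radius_range_px) * (1 + contour_perturbation) +
      max(bilayer_spacing_A) / (2 * pixel_size) + mask_halfwidth_px +
      3 * ring_sigma_px
    image_size <- max(256L, as.integer(ceiling(
      sqrt(max(n_top, 1) * pi * outer^2 / 0.30) + 2 * margin_px)))
  }

  with_seed(seed, {
    specs <- place_vesicles(
      n_top = n_top, n_nested = n_nested, image_size = image_size,
      pixel_size = pixel_size, radius_range_px = radius_range_px,
      bilayer_spacing_A = bilayer_spacing_A,
      enclosure_gap_A = enclosure_gap_A,
      min_child_radius_px = min_child_radius_px,
      contour_perturbation = contour_perturbation,
      ring_sigma_px = ring_sigma_px,
      mask_halfwidth_px = mask_halfwidth_px,
      margin_px = margin_px, max_retries = max_retries)

    intensity <- matrix(0, image_size, image_size)
    if (noise_sigma > 0) {
      intensity <- matrix(rnorm(image_size^2, 0, noise_sigma),
                          image_size, image_size)
    }
    mask <- matrix(0L, image_size, image_size)

    truth <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      rend <- render_vesicle(sp, image_size, pixel_size,
                             ring_sigma_px, mask_halfwidth_px)
      intensity[rend$box_rows, rend$box_cols] <-
        intensity[rend$box_rows, rend$box_cols] - rend$dip
      mask[rend$box_rows, rend$box_cols] <-
        pmax(mask[rend$box_rows, rend$box_cols], rend$mask)
      truth[[i]] <- tibble(
        id = i,
        center_row = sp$center[1], center_col = sp$center[2],
        radius_px = sp$radius,
        bilayer_spacing_A = sp$spacing,
        perimeter_nm = contour_perimeter(sp, pixel_size),
        parent = sp$parent %||% NA_integer_,
        enclosure_distance_A = NA_real_
      )
    }
    truth <- dplyr::bind_rows(truth)
    # exact enclosure distances from dense contours
    for (i in seq_len(nrow(truth))) {
      p <- truth$parent[i]
      if (!is.na(p)) {
        truth$enclosure_distance_A[i] <- contour_min_distance(
          specs[[i]], specs[[p]]) * pixel_size
      }
    }

    structure(list(intensity = intensity, mask = mask,
                   pixel_size = pixel_size, truth = truth, seed = seed,
                   specs = specs),
              class = "synthetic_field")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field> %d x %d px (%.1f A/px), %d vesicles (%d nested)\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size,
              nrow(x$truth), sum(!is.na(x$truth$parent))))
  invisible(x)
}

# -- internal geometry -------------------------------------------------------

# vesicle contour radius as a function of angle (low-order Fourier shape)
contour_radius <- function(sp, theta) {
  r <- rep(sp$radius, length(theta))
  if (!is.null(sp$fourier) && nrow(sp$fourier) > 0) {
    for (j in seq_len(nrow(sp$fourier))) {
      r <- r + sp$radius * sp$fourier$amp[j] *
        cos(sp$fourier$k[j] * theta + sp$fourier$phase[j])
    }
  }
  r
}

contour_points <- function(sp, n = 4096) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- contour_radius(sp, theta)
  cbind(row = sp$center[1] + r * sin(theta),
        col = sp$center[2] + r * cos(theta))
}

# exact perimeter (nm) by dense polygonal integration of the true contour
contour_perimeter <- function(sp, pixel_size, n = 8192) {
  pts <- contour_points(sp, n)
  d <- sqrt(rowSums((pts - pts[c(2:n, 1), ])^2))
  sum(d) * pixel_size / 10
}

contour_min_distance <- function(sp_a, sp_b, n = 1024) {
  a <- contour_points(sp_a, n)
  b <- contour_points(sp_b, n)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2))
}

new_fourier <- function(amplitude) {
  if (amplitude <= 0) return(NULL)
  k <- 2:4
  amp <- runif(3)
  amp <- amp / sum(amp) * amplitude
  tibble(k = k, amp = amp, phase = runif(3, 0, 2 * pi))
}

place_vesicles <- function(n_top, n_nested, image_size, pixel_size,
                           radius_range_px, bilayer_spacing_A,
                           enclosure_gap_A, min_child_radius_px,
                           contour_perturbation, ring_sigma_px,
                           mask_halfwidth_px, margin_px, max_retries) {
  hs_of <- function(spacing) spacing / (2 * pixel_size)
  outer_extent <- function(sp) {
    max(contour_radius(sp, seq(0, 2 * pi, length.out = 256))) +
      hs_of(sp$spacing) + mask_halfwidth_px + 3 * ring_sigma_px
  }
  gap_px <- enclosure_gap_A / pixel_size
  specs <- list()

  # parents (hosting a nested child) need room for the child plus the gap
  parent_min_r <- min_child_radius_px + max(gap_px) + 1
  if (n_nested > 0 && parent_min_r > max(radius_range_px)) {
    abort("placement failure: radius range too small to host nested vesicles.")
  }

  for (i in seq_len(n_top)) {
    is_parent <- i <= n_nested
    r_lo <- if (is_parent) max(radius_range_px[1], parent_min_r) else
      radius_range_px[1]
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      sp <- list(
        radius = runif(1, r_lo, radius_range_px[2]),
        spacing = runif(1, bilayer_spacing_A[1], bilayer_spacing_A[2]),
        fourier = new_fourier(contour_perturbation),
        parent = NULL
      )
      ext <- outer_extent(sp)
      lim <- c(margin_px + ext, image_size - margin_px - ext)
      if (lim[1] >= lim[2]) next
      sp$center <- runif(2, lim[1], lim[2])
      ok <- TRUE
      for (other in specs) {
        dc <- sqrt(sum((sp$center - other$center)^2))
        if (dc < ext + outer_extent(other) + margin_px) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        specs[[length(specs) + 1]] <- sp
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        "placement failure: could not place vesicle %d of %d after %d retries (field too crowded).",
        i, n_top, max_retries))
    }
  }

  # nested children, one per parent (parents are specs 1..n_nested)
  for (j in seq_len(n_nested)) {
    parent <- specs[[j]]
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      gap <- runif(1, gap_px[1], gap_px[2])
      spacing <- runif(1, bilayer_spacing_A[1], bilayer_spacing_A[2])
      # mask annuli of parent and child must stay separate after
      # rasterization: clearance above the pixel diagonal avoids
      # 8-connected merging
      sep_needed <- hs_of(parent$spacing) + hs_of(spacing) +
        2 * mask_halfwidth_px + 1.6
      if (gap <= sep_needed) next
      r_max <- parent$radius - gap
      if (r_max < min_child_radius_px) next
      child_r <- runif(1, min_child_radius_px, r_max)
      offset <- parent$radius - gap - child_r
      ang <- runif(1, 0, 2 * pi)
      sp <- list(
        radius = child_r, spacing = spacing,
        fourier = new_fourier(contour_perturbation),
        parent = j,
        center = parent$center + offset * c(sin(ang), cos(ang))
      )
      # perturbed contours: verify the realized clearance numerically
      if (contour_perturbation > 0 &&
          contour_min_distance(sp, parent, 512) <= sep_needed) next
      specs[[length(specs) + 1]] <- sp
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf(
        "placement failure: could not nest a child inside parent %d after %d retries.",
        j, max_retries))
    }
  }
  specs
}

render_vesicle <- function(sp, image_size, pixel_size,
                           ring_sigma_px, mask_halfwidth_px) {
  hs <- sp$spacing / (2 * pixel_size)
  ext <- max(contour_radius(sp, seq(0, 2 * pi, length.out = 256))) + hs +
    mask_halfwidth_px + 3 * ring_sigma_px
  rows <- max(1L, floor(sp$center[1] - ext)):min(image_size,
                                                 ceiling(sp$center[1] + ext))
  cols <- max(1L, floor(sp$center[2] - ext)):min(image_size,
                                                 ceiling(sp$center[2] + ext))
  dr <- outer(rows - sp$center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - sp$center[2])
  d <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  rm_ <- matrix(contour_radius(sp, as.vector(theta)), nrow(d), ncol(d))
  s <- d - rm_  # signed distance from the skeleton circle
  dip <- exp(-(s - hs)^2 / (2 * ring_sigma_px^2)) +
    exp(-(s + hs)^2 / (2 * ring_sigma_px^2))
  mask <- (abs(s) <= hs + mask_halfwidth_px) * 1L
  list(box_rows = rows, box_cols = cols, dip = dip,
       mask = matrix(as.integer(mask), nrow(d), ncol(d)))
}

#' Write a synthetic field to disk
#'
#' Writes the intensity image (32-bit float TIFF), the mask (8-bit TIFF) and
#' the ground-truth table (JSON) into a directory.
#'
#' @param field A [generate_vesicle_field()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_field <- function(field, dir) {
  stopifnot(inherits(field, "synthetic_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    intensity = file.path(dir, "intensity.tif"),
    mask = file.path(dir, "mask.tif"),
    truth = file.path(dir, "truth.json")
  )
  rng <- range(field$intensity)
  scaled <- if (diff(rng) > 0) (field$intensity - rng[1]) / diff(rng) else
    field$intensity * 0
  tiff::writeTIFF(scaled, paths["intensity"], bits.per.sample = 32L)
  tiff::writeTIFF(field$mask * 1.0, paths["mask"], bits.per.sample = 8L)
  jsonlite::write_json(
    list(pixel_size = field$pixel_size, seed = field$seed,
         truth = field$truth),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
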