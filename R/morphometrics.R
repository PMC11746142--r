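#' Perimeter of a closed membrane trace
#'
#' Sum of Euclidean distances between neighbouring skeleton points
#' (including the closing segment), scaled by the pixel size and reported
#' in nanometres. Dividing by pi gives the equivalent circular diameter.
#'
#' Summing raw pixel-centre steps systematically overestimates the length
#' of a smooth digitized curve (the staircase of 1 and sqrt(2) steps adds
#' 5-10 percent). A circular moving average over `smooth_window` points is
#' therefore applied to the trace coordinates before summing; it removes
#' the staircase while displacing the path by well under a pixel. Traces
#' shorter than three window widths are summed raw, so tiny hand-made
#' polygons are measured exactly.
#'
#' @param trace A closed `membrane_trace`.
#' @param smooth_window Moving-average window in points (default 5);
#'   0 or 1 disables smoothing.
#' @return Perimeter in nm.
#' @export
vesicle_perimeter <- function(trace, smooth_window = 5) {
  stopifnot(inherits(trace, "membrane_trace"))
  if (!isTRUE(trace$closed)) abort("perimeter is defined for closed traces only.")
  p <- trace$points
  n <- nrow(p)
  if (smooth_window > 1 && n > 3 * smooth_window) {
    p <- circular_smooth(p, smooth_window)
  }
  d <- sqrt(rowSums((p - p[c(2:n, 1), , drop = FALSE])^2))
  sum(d) * trace$pixel_size / 10
}

# circular moving average of an ordered closed polygon's vertices
circular_smooth <- function(p, w) {
  n <- nrow(p)
  half <- (w - 1) %/% 2
  out <- p * 0
  for (k in (-half):half) {
    out <- out + p[((seq_len(n) - 1 + k) %% n) + 1, , drop = FALSE]
  }
  out / (2 * half + 1)
}

#' Detect nesting relations among closed vesicles
#'
#' Vesicle A is enclosed by vesicle B when A's skeleton points lie inside
#' the closed polygon of B's trace (even-odd rule). The default requires
#' every point inside (strict containment); `rule = "majority"` accepts a
#' vesicle when more than half of its points fall inside. A vesicle can be
#' enclosed by, and enclose, multiple other vesicles.
#'
#' @param traces A list of closed `membrane_trace`s.
#' @param rule `"all"` (default) or `"majority"`.
#' @return A tibble of directed relations with columns `inner` and `outer`
#'   (indices into `traces`).
#' @export
detect_nesting <- function(traces, rule = c("all", "majority")) {
  rule <- match.arg(rule)
  if (!all(vapply(traces, function(t) isTRUE(t$closed), logical(1)))) {
    abort("all traces must be closed.")
  }
  n <- length(traces)
  # bounding-box prescreen: A can only be inside B if A's box is inside B's
  boxes <- t(vapply(traces, function(t)
    c(range(t$points[, 1]), range(t$points[, 2])), numeric(4)))
  rel <- list()
  for (j in seq_len(n)) {
    bnd <- traces[[j]]$points
    for (i in seq_len(n)) {
      if (i == j) next
      if (boxes[i, 1] < boxes[j, 1] || boxes[i, 2] > boxes[j, 2] ||
          boxes[i, 3] < boxes[j, 3] || boxes[i, 4] > boxes[j, 4]) next
      inside <- mgcv::in.out(rbind(bnd, bnd[1, , drop = FALSE]),
                             traces[[i]]$points)
      hit <- if (rule == "all") all(inside) else mean(inside) > 0.5
      if (hit) rel[[length(rel) + 1]] <- c(inner = i, outer = j)
    }
  }
  out <- if (length(rel) == 0) {
    tibble(inner = integer(), outer = integer())
  } else {
    as_tibble(do.call(rbind, rel))
  }
  if (nrow(out) > 0 &&
      nrow(dplyr::inner_join(out, out,
                             by = c(inner = "outer", outer = "inner"))) > 0) {
    abort("nesting relation contains a cycle; traces are inconsistent.")
  }
  out
}

#' Enclosure distance between two nested vesicles
#'
#' Minimum Euclidean distance between the skeleton points of an enclosed
#' vesicle and its encloser, in Angstrom.
#'
#' @param inner,outer Closed `membrane_trace`s; `inner` must lie inside
#'   `outer` (checked unless `check = FALSE`).
#' @param check Verify the containment precondition (default `TRUE`).
#' @return Distance in Angstrom.
#' @export
enclosure_distance <- function(inner, outer, check = TRUE) {
  stopifnot(inherits(inner, "membrane_trace"),
            inherits(outer, "membrane_trace"))
  if (check) {
    bnd <- outer$points
    if (!all(mgcv::in.out(rbind(bnd, bnd[1, , drop = FALSE]),
                          inner$points))) {
      abort("`inner` is not enclosed by `outer`; enclosure distance undefined.")
    }
  }
  a <- inner$points
  b <- outer$points
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2)) * inner$pixel_size
}

#' Bilayer thickness from the radially averaged membrane profile
#'
#' Samples the image intensity along the local normal at every skeleton
#' point (bilinear interpolation, 0.5 px steps over +/- `half_width_A`),
#' averages the profiles over the whole trace, and measures the separation
#' of the two deepest local intensity minima — the two bilayer leaflets —
#' after three-point parabolic refinement. Returns `NA` when fewer than two
#' minima are found or the separation falls outside the plausible window.
#'
#' @param trace A `membrane_trace`.
#' @param intensity The grayscale image the trace was derived from
#'   (membranes dark).
#' @param half_width_A Normal sampling half-width in Angstrom (default 60).
#' @param step_px Sampling step along the normal in pixels (default 0.5).
#' @param thickness_window_A Plausible thickness range in Angstrom
#'   (default 20-100).
#' @param secant_k Neighbour offset used for the local tangent (default 3).
#' @return Thickness in Angstrom, or `NA_real_` when undefined.
#' @export
bilayer_thickness <- function(trace, intensity, half_width_A = 60,
                              step_px = 0.5,
                              thickness_window_A = c(20, 100),
                              secant_k = 3) {
  stopifnot(inherits(trace, "membrane_trace"), is.matrix(intensity))
  p <- trace$points
  n <- nrow(p)
  px <- trace$pixel_size
  hw_px <- half_width_A / px
  offsets <- seq(-hw_px, hw_px, by = step_px)

  # local normals from the +/- k secant (cyclic for closed traces)
  k <- secant_k
  idx_prev <- if (trace$closed) ((seq_len(n) - 1 - k) %% n) + 1 else
    pmax(seq_len(n) - k, 1)
  idx_next <- if (trace$closed) ((seq_len(n) - 1 + k) %% n) + 1 else
    pmin(seq_len(n) + k, n)
  tang <- p[idx_next, , drop = FALSE] - p[idx_prev, , drop = FALSE]
  len <- sqrt(rowSums(tang^2))
  normal <- cbind(-tang[, 2], tang[, 1]) / len

  rows <- outer(p[, 1], rep(1, length(offsets))) + normal[, 1] %o% offsets
  cols <- outer(p[, 2], rep(1, length(offsets))) + normal[, 2] %o% offsets
  if (min(rows) < 1 || min(cols) < 1 ||
      max(rows) > nrow(intensity) || max(cols) > ncol(intensity)) {
    abort("trace too close to the image border for the requested half width.")
  }
  prof <- colMeans(matrix(bilinear_sample(intensity, rows, cols),
                          nrow = n))

  m <- length(prof)
  i <- 2:(m - 1)
  is_min <- prof[i] < prof[i - 1] & prof[i] <= prof[i + 1]
  minima <- i[is_min]
  if (length(minima) < 2) return(NA_real_)
  deepest <- minima[order(prof[minima])][1:2]
  pos <- vapply(sort(deepest), function(j)
    parabolic_vertex(offsets, -prof, j), numeric(1))
  thickness <- abs(diff(pos)) * px
  if (thickness < thickness_window_A[1] ||
      thickness > thickness_window_A[2]) {
    return(NA_real_)
  }
  thickness
}

bilinear_sample <- function(img, rows, cols) {
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  r1 <- pmin(r0 + 1, nrow(img)); c1 <- pmin(c0 + 1, ncol(img))
  img[cbind(as.vector(r0), as.vector(c0))] * as.vector((1 - fr) * (1 - fc)) +
    img[cbind(as.vector(r1), as.vector(c0))] * as.vector(fr * (1 - fc)) +
    img[cbind(as.vector(r0), as.vector(c1))] * as.vector((1 - fr) * fc) +
    img[cbind(as.vector(r1), as.vector(c1))] * as.vector(fr * fc)
}

#' Full vesicle morphometrics of a segmented field
#'
#' Runs the complete per-image analysis: skeletonization, closed-vesicle
#' selection, perimeter, nesting, enclosure distance and (when an intensity
#' image is given) bilayer thickness. This is the per-micrograph entry
#' point; feed the result to [summarize_vesicles()] for field-level
#' statistics.
#'
#' @param mask Binary segmentation matrix.
#' @param pixel_size Pixel size in Angstrom per pixel.
#' @param intensity Optional grayscale image matched to `mask` for
#'   thickness estimation.
#' @param nesting_rule Containment rule passed to [detect_nesting()].
#' @inheritParams bilayer_thickness
#' @inheritParams skeletonize
#'
#' @return A tibble with one row per closed vesicle: `id`, `n_points`,
#'   `perimeter_nm`, `diameter_nm` (perimeter / pi), `n_enclosed_by`,
#'   `n_encloses`, `is_double_membrane`, `enclosure_distance_A` (minimum
#'   over enclosers, `NA` if none) and `thickness_A`. The trace list and
#'   the number of discarded ambiguous components travel as attributes
#'   `traces` and `n_discarded`.
#' @export
measure_vesicles <- function(mask, pixel_size, intensity = NULL,
                             max_branch_nodes = 0, min_points = 8,
                             nesting_rule = "all", half_width_A = 60,
                             thickness_window_A = c(20, 100)) {
  traces <- skeletonize(mask, pixel_size, max_branch_nodes, min_points)
  closed <- select_closed(traces)
  n <- length(closed)
  if (n == 0) {
    out <- tibble(id = integer(), n_points = integer(),
                  perimeter_nm = numeric(), diameter_nm = numeric(),
                  n_enclosed_by = integer(), n_encloses = integer(),
                  is_double_membrane = logical(),
                  enclosure_distance_A = numeric(),
                  thickness_A = numeric())
    return(structure(out, traces = closed,
                     n_discarded = attr(traces, "n_discarded")))
  }
  rel <- detect_nesting(closed, rule = nesting_rule)
  perim <- vapply(closed, vesicle_perimeter, numeric(1))

  encl_dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    outers <- rel$outer[rel$inner == i]
    if (length(outers) > 0) {
      encl_dist[i] <- min(vapply(outers, function(j)
        enclosure_distance(closed[[i]], closed[[j]], check = FALSE),
        numeric(1)))
    }
  }
  thick <- rep(NA_real_, n)
  if (!is.null(intensity)) {
    thick <- vapply(closed, function(tr)
      bilayer_thickness(tr, intensity, half_width_A = half_width_A,
                        thickness_window_A = thickness_window_A),
      numeric(1))
  }
  out <- tibble(
    id = seq_len(n),
    n_points = vapply(closed, function(t) nrow(t$points), integer(1)),
    perimeter_nm = perim,
    diameter_nm = perim / pi,
    n_enclosed_by = vapply(seq_len(n), function(i)
      sum(rel$inner == i), integer(1)),
    n_encloses = vapply(seq_len(n), function(i)
      sum(rel$outer == i), integer(1)),
    is_double_membrane = vapply(seq_len(n), function(i)
      any(rel$inner == i), logical(1)),
    enclosure_distance_A = encl_dist,
    thickness_A = thick
  )
  structure(out, traces = closed, n_discarded = attr(traces, "n_discarded"))
}

#' Field-level morphometric summary
#'
#' Means over the per-vesicle measurements plus the double-membrane
#' fraction: the share of closed vesicles enclosed by at least one other
#' vesicle, with all closed vesicles in the denominator.
#'
#' @param vesicles A per-vesicle tibble from [measure_vesicles()] (needs
#'   columns `perimeter_nm`, `is_double_membrane`; optional
#'   `thickness_A`, `enclosure_distance_A`).
#' @return A one-row tibble: `n`, `mean_perimeter_nm`, `mean_diameter_nm`,
#'   `mean_thickness_A`, `n_thickness`, `mean_enclosure_distance_A`,
#'   `double_membrane_fraction`.
#' @export
summarize_vesicles <- function(vesicles) {
  if (!is.data.frame(vesicles) || nrow(vesicles) == 0) {
    abort("`vesicles` must contain at least one vesicle.")
  }
  thick <- if ("thickness_A" %in% names(vesicles)) vesicles$thickness_A else
    rep(NA_real_, nrow(vesicles))
  encl <- if ("enclosure_distance_A" %in% names(vesicles)) {
    vesicles$enclosure_distance_A
  } else {
    rep(NA_real_, nrow(vesicles))
  }
  tibble(
    n = nrow(vesicles),
    mean_perimeter_nm = mean(vesicles$perimeter_nm),
    mean_diameter_nm = mean(vesicles$perimeter_nm) / pi,
    mean_thickness_A = if (all(is.na(thick))) NA_real_ else
      mean(thick, na.rm = TRUE),
    n_thickness = sum(!is.na(thick)),
    mean_enclosure_distance_A = if (all(is.na(encl))) NA_real_ else
      mean(encl, na.rm = TRUE),
    double_membrane_fraction = mean(vesicles$is_double_membrane)
  )
}
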