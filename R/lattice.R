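#' Helical symmetry descriptor
#'
#' A helical lattice is described by the screw operation relating consecutive
#' asymmetric units: an axial rise (Angstrom), an azimuthal twist (degrees)
#' and an n-fold cyclic symmetry Cn applied at every step. PspA rods of
#' different diameters each refine to one such parameter set.
#'
#' @param n Cyclic order (Cn), a positive integer.
#' @param rise Axial rise per helical step in Angstrom, positive.
#' @param twist Azimuthal twist per helical step in degrees, in (-180, 180].
#'
#' @return An object of class `helical_symmetry` (a named list).
#' @examples
#' helical_symmetry(2, 5.75, 34.4)  # the 200 A rod class
#' @export
helical_symmetry <- function(n, rise, twist) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer (cyclic order of Cn).")
  }
  check_number(rise, "rise")
  if (rise <= 0) abort("`rise` must be positive.")
  check_number(twist, "twist")
  if (twist <= -180 || twist > 180) {
    abort("`twist` must lie in (-180, 180] degrees.")
  }
  structure(list(n = as.integer(n), rise = rise, twist = twist),
            class = "helical_symmetry")
}

#' @export
format.helical_symmetry <- function(x, ...) {
  sprintf("C%d, %.2f A, %.1f deg", x$n, x$rise, x$twist)
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat("<helical_symmetry> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Helical symmetry table of the PspA + ATP rod classes
#'
#' Returns the refined symmetry parameters of the eleven PspA rod classes
#' determined in the presence of ATP (diameters 180-365 Angstrom), as a
#' tibble with one row per diameter class, together with derived per-subunit
#' quantities.
#'
#' @param monomer_mass Monomer mass in kDa used for the mass-per-length
#'   column. Defaults to 25.3 kDa (PspA).
#' @param path Optional path to a CSV with columns `diameter_A`, `cyclic_n`,
#'   `rise_A`, `twist_deg`; defaults to the table shipped with the package.
#'
#' @return A tibble with columns `diameter_A`, `cyclic_n`, `rise_A`,
#'   `twist_deg`, `rise_per_asu_A` and `mass_per_length_kDa_A`.
#' @examples
#' pspa_symmetry_table()
#' @export
pspa_symmetry_table <- function(monomer_mass = 25.3, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pspa_atp_symmetry.csv",
                        package = "rodmorph", mustWork = TRUE)
  }
  tab <- as_tibble(read.csv(path))
  stopifnot(all(c("diameter_A", "cyclic_n", "rise_A", "twist_deg") %in%
                  names(tab)))
  dplyr::mutate(
    tab,
    rise_per_asu_A = .data$rise_A / .data$cyclic_n,
    mass_per_length_kDa_A = purrr::map2_dbl(
      .data$cyclic_n, .data$rise_A,
      \(n, r) mass_per_length(helical_symmetry(n, r, 0), monomer_mass)
    )
  )
}

#' Mass-per-length of a helical polymer
#'
#' The mass packed per axial Angstrom of the helical lattice:
#' `n * monomer_mass / rise`. The per-asymmetric-unit rise `rise / n` is the
#' companion quantity (returned by [rise_per_asu()]).
#'
#' @param sym A [helical_symmetry()].
#' @param monomer_mass Monomer mass in kDa, positive.
#'
#' @return Mass per length in kDa per Angstrom.
#' @examples
#' mass_per_length(helical_symmetry(2, 5.75, 34.4), 25.3)  # 8.80 kDa/A
#' @export
mass_per_length <- function(sym, monomer_mass) {
  stopifnot(inherits(sym, "helical_symmetry"))
  check_number(monomer_mass, "monomer_mass")
  if (monomer_mass <= 0) abort("`monomer_mass` must be positive.")
  sym$n * monomer_mass / sym$rise
}

#' @rdname mass_per_length
#' @export
rise_per_asu <- function(sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  sym$rise / sym$n
}

#' Number of monomers in a rod of given length
#'
#' A rod of length L (micrometre) built on a lattice with per-step rise
#' `rise` and cyclic order n contains `L(Angstrom) * n / rise` monomers.
#' A 2.6 micrometre rod of the 215 Angstrom class (C1, rise 2.52 Angstrom)
#' holds roughly ten thousand monomers.
#'
#' @param rod_length_um Rod length in micrometres, non-negative.
#' @param sym A [helical_symmetry()].
#' @param signif_digits Optional number of significant digits to round the
#'   count to (e.g. 1 reproduces order-of-magnitude reporting). `NULL` (the
#'   default) returns the unrounded count.
#'
#' @return Monomer count (numeric).
#' @examples
#' monomer_count(2.6, helical_symmetry(1, 2.52, 130.2), signif_digits = 1)
#' @export
monomer_count <- function(rod_length_um, sym, signif_digits = NULL) {
  check_number(rod_length_um, "rod_length_um", lower = 0)
  stopifnot(inherits(sym, "helical_symmetry"))
  count <- rod_length_um * 1e4 * sym$n / sym$rise
  if (!is.null(signif_digits)) count <- signif(count, signif_digits)
  count
}

#' Local ATP turnover after amplification
#'
#' If only a small fraction of the sites along a rod hydrolyse ATP at a given
#' time, the local turnover exceeds the bulk rate by the amplification
#' factor. A bulk activity of 3 per hour amplified 1000-fold corresponds to
#' 3000 per hour, i.e. 50 ATP per minute.
#'
#' @param bulk_rate_per_h Bulk ATPase rate in 1/h, non-negative.
#' @param amplification Amplification factor, at least 1.
#'
#' @return A tibble with columns `rate_per_h` and `rate_per_min`.
#' @examples
#' local_turnover(3, 1000)
#' @export
local_turnover <- function(bulk_rate_per_h, amplification) {
  check_number(bulk_rate_per_h, "bulk_rate_per_h", lower = 0)
  check_number(amplification, "amplification", lower = 1)
  per_h <- bulk_rate_per_h * amplification
  tibble(rate_per_h = per_h, rate_per_min = per_h / 60)
}

#' Lattice neighbour offsets on the helical cylinder
#'
#' Enumerates chain-index offsets around a reference subunit and ranks them
#' by centroid-to-centroid distance on the cylinder of radius R. An offset of
#' k helical steps and c cyclic copies sits at azimuth
#' `k * twist + c * 360 / n` degrees and height `k * rise`; the in-plane
#' separation is the chord `2 R sin(dphi / 2)`.
#'
#' Chain indexing is helical-step-major, cyclic-copy-minor: the chain index
#' reported is `k * n + c`.
#'
#' @param sym A [helical_symmetry()].
#' @param radius Cylinder radius in Angstrom, positive.
#' @param k_max Largest helical step offset searched (both signs), >= 1.
#'
#' @return A tibble sorted by ascending `distance_A` with columns `step_k`,
#'   `cyclic_c`, `chain_offset`, `dphi_deg`, `dz_A`, `distance_A`.
#' @examples
#' neighbor_offsets(helical_symmetry(1, 2.52, 130.2), radius = 107.5, k_max = 30)
#' @export
neighbor_offsets <- function(sym, radius, k_max = 30L) {
  stopifnot(inherits(sym, "helical_symmetry"))
  check_number(radius, "radius")
  if (radius <= 0) abort("`radius` must be positive.")
  if (k_max < 1) abort("`k_max` must be at least 1.")
  grid <- tidyr::expand_grid(step_k = seq.int(-k_max, k_max),
                             cyclic_c = seq_len(sym$n) - 1L)
  grid <- dplyr::filter(grid, !(.data$step_k == 0 & .data$cyclic_c == 0))
  out <- dplyr::mutate(
    grid,
    chain_offset = .data$step_k * sym$n + .data$cyclic_c,
    dphi_deg = ((.data$step_k * sym$twist + .data$cyclic_c * 360 / sym$n +
                   180) %% 360) - 180,
    dz_A = .data$step_k * sym$rise,
    distance_A = sqrt((2 * radius * sin(deg2rad(abs(.data$dphi_deg)) / 2))^2 +
                        .data$dz_A^2)
  )
  dplyr::arrange(out, .data$distance_A, abs(.data$step_k), .data$cyclic_c)
}
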