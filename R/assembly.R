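#' Build an idealized helical assembly from a monomer
#'
#' Applies the helical screw operation to a monomer to build a rod: chain
#' `k * n + c` (helical step k, cyclic copy c) is the monomer placed at
#' azimuth `k * twist + c * 360 / n` degrees and height `k * rise`, with the
#' monomer's centroid at distance `radius` from the helical (z) axis. The
#' chain count is `n_steps * n`; the symmetries of the PspA rod classes with
#' `n_steps * n = 60` reproduce the sixty-monomer assemblies used for
#' model refinement.
#'
#' @param monomer A `monomer_model` (e.g. [toy_monomer()]).
#' @param sym A [helical_symmetry()].
#' @param n_steps Number of helical steps (>= 1).
#' @param radius Centroid radius in Angstrom.
#' @param rod_diameter Optional diameter label stored with the assembly.
#'
#' @return An object of class `assembly_model`: list with `chains` (named
#'   list of C-alpha tibbles), `info` (tibble with chain, step, copy,
#'   azimuth and height), `segments`, `symmetry` and `rod_diameter`.
#' @examples
#' asm <- generate_helical_assembly(toy_monomer(),
#'                                  helical_symmetry(2, 5.75, 34.4),
#'                                  n_steps = 3, radius = 100)
#' length(asm$chains)  # 6
#' @export
generate_helical_assembly <- function(monomer, sym, n_steps, radius,
                                      rod_diameter = NULL) {
  stopifnot(inherits(monomer, "monomer_model"),
            inherits(sym, "helical_symmetry"))
  if (n_steps < 1 || n_steps != round(n_steps)) {
    abort("`n_steps` must be a positive integer.")
  }
  check_number(radius, "radius", lower = 0)

  xyz0 <- monomer_xyz(monomer)
  centroid <- colMeans(xyz0)
  placed <- sweep(xyz0, 2, centroid)  # centre, then push out to the radius
  placed <- sweep(placed, 2, c(radius, 0, 0), "+")

  info <- tidyr::expand_grid(step = seq_len(n_steps) - 1L,
                             copy = seq_len(sym$n) - 1L)
  info <- dplyr::mutate(
    info,
    index = .data$step * sym$n + .data$copy,
    chain = chain_id(.data$index),
    azimuth_deg = .data$step * sym$twist + .data$copy * 360 / sym$n,
    z_A = .data$step * sym$rise
  )

  chains <- purrr::pmap(info, function(step, copy, index, chain,
                                       azimuth_deg, z_A) {
    R <- rotation_about_axis(c(0, 0, 1), azimuth_deg)
    xyz <- placed %*% t(R)
    xyz[, 3] <- xyz[, 3] + z_A
    tibble(resno = monomer$atoms$resno,
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  names(chains) <- info$chain

  structure(list(chains = chains, info = info,
                 segments = monomer$segments, symmetry = sym,
                 rod_diameter = rod_diameter, source = "generated"),
            class = "assembly_model")
}

chain_id <- function(index) {
  alphabet <- c(LETTERS, letters, as.character(0:9))
  if (any(index >= length(alphabet))) {
    abort("more than 62 chains cannot be given single-character PDB ids.")
  }
  alphabet[index + 1L]
}

#' @export
print.assembly_model <- function(x, ...) {
  cat(sprintf("<assembly_model> %d chains x %d residues%s\n",
              length(x$chains), nrow(x$chains[[1]]),
              if (!is.null(x$rod_diameter))
                sprintf(" (rod class %s A)", x$rod_diameter) else ""))
  invisible(x)
}

#' Extract one chain of an assembly as a monomer model
#'
#' @param assembly An `assembly_model`.
#' @param chain Chain identifier (name in `assembly$chains`) or index.
#' @return A `monomer_model`.
#' @export
chain_monomer <- function(assembly, chain) {
  stopifnot(inherits(assembly, "assembly_model"))
  atoms <- assembly$chains[[chain]]
  if (is.null(atoms)) abort(sprintf("chain `%s` not found.", chain))
  new_monomer(atoms, assembly$segments)
}

#' Write an assembly as a PDB file
#'
#' C-alpha-only PDB output via bio3d, one chain identifier per symmetry
#' copy. Coordinates are stored at the standard 0.001 Angstrom precision.
#'
#' @param assembly An `assembly_model` (or a `monomer_model`, written as
#'   chain A).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path) {
  if (inherits(assembly, "monomer_model")) {
    chains <- list(A = assembly$atoms)
  } else {
    stopifnot(inherits(assembly, "assembly_model"))
    chains <- assembly$chains
  }
  atoms <- dplyr::bind_rows(purrr::imap(chains, \(a, ch)
    dplyr::mutate(a, chain = ch)))
  n <- nrow(atoms)
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = atoms$resno,
                   chain = atoms$chain, resid = rep("ALA", n),
                   elety = rep("CA", n), eleno = seq_len(n))
  invisible(path)
}

#' Load an atomic model (C-alpha trace) from a PDB file
#'
#' Reads all chains of a PDB file, keeps the C-alpha atoms, and returns an
#' `assembly_model` preserving residue numbering.
#'
#' @param path PDB file path.
#' @param rod_diameter Optional diameter label to attach.
#' @param segments Optional named list of residue ranges to attach.
#' @return An `assembly_model`.
#' @export
load_model <- function(path, rod_diameter = NULL, segments = list()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) abort(sprintf(
                    "could not parse `%s` as PDB: %s", path,
                    conditionMessage(e))))
  at <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0) abort(sprintf("no C-alpha atoms found in %s", path))
  chains <- split(at, at$chain)
  chains <- purrr::map(chains, \(a) tibble(resno = a$resno, x = a$x,
                                           y = a$y, z = a$z))
  info <- tibble(chain = names(chains),
                 step = NA_integer_, copy = NA_integer_,
                 index = seq_along(chains) - 1L,
                 azimuth_deg = NA_real_, z_A = NA_real_)
  structure(list(chains = chains, info = info, segments = segments,
                 symmetry = NULL, rod_diameter = rod_diameter,
                 source = path),
            class = "assembly_model")
}
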