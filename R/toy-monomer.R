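#' Ideal alpha-helical C-alpha trace
#'
#' Places `n` consecutive C-alpha positions on an ideal alpha-helix (1.5
#' Angstrom rise and 100 degree twist per residue on a 2.3 Angstrom helix
#' radius) whose axis starts at `origin` and points along `axis`.
#'
#' @param n Number of residues.
#' @param origin Axis start point (length-3 numeric).
#' @param axis Axis direction (length-3 numeric, need not be unit).
#' @param phase Initial azimuthal phase in degrees.
#' @return An `n x 3` matrix of coordinates in Angstrom.
#' @export
ca_helix <- function(n, origin = c(0, 0, 0), axis = c(0, 0, 1), phase = 0) {
  stopifnot(n >= 1, length(origin) == 3, length(axis) == 3)
  u <- axis / sqrt(sum(axis^2))
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  i <- seq_len(n) - 1
  ang <- deg2rad(phase + 100 * i)
  t(origin + outer(u, 1.5 * i)) + 2.3 * (outer(cos(ang), e1) +
                                           outer(sin(ang), e2))
}

straight_trace <- function(n, from, dir, spacing = 3.8) {
  u <- dir / sqrt(sum(dir^2))
  t(from + outer(u, spacing * seq_len(n)))
}

#' Synthetic hairpin-like test monomer
#'
#' Builds a 200-residue C-alpha trace (residues 22-221) laid out as an
#' antiparallel helical hairpin followed by two further helices, with a
#' segment map mimicking PspA residue numbering (alpha1, alpha2+3, alpha4,
#' alpha5 and the connecting loops). This is an idealized geometric stand-in
#' for testing superposition, hinge-angle and contact analyses; it is
#' explicitly not the real PspA fold.
#'
#' @return An object of class `monomer_model`: a list with `atoms` (tibble
#'   `resno`, `x`, `y`, `z`) and `segments` (named list of residue ranges).
#' @examples
#' m <- toy_monomer()
#' m$segments$a4
#' @export
toy_monomer <- function() {
  seg <- list(
    a1 = 22:84, loop_hairpin = 85:89, a23 = 90:155,
    loop_a3a4 = 156:165, a4 = 166:186, loop_a4a5 = 187:189,
    a5 = 190:217, tail = 218:221
  )
  coords <- list()
  # alpha1 up the hairpin
  coords$a1 <- ca_helix(length(seg$a1), origin = c(0, 0, 0),
                        axis = c(0, 0, 1))
  p <- coords$a1[nrow(coords$a1), ]
  # short loop over to the antiparallel alpha2+3 strand
  coords$loop_hairpin <- straight_trace(length(seg$loop_hairpin), p,
                                        c(1, 0.3, 0.1))
  p <- coords$loop_hairpin[nrow(coords$loop_hairpin), ]
  coords$a23 <- ca_helix(length(seg$a23), origin = p + c(2, 0, -2),
                         axis = c(0.05, 0, -1))
  p <- coords$a23[nrow(coords$a23), ]
  coords$loop_a3a4 <- straight_trace(length(seg$loop_a3a4), p,
                                     c(0.5, 0.2, -1))
  p <- coords$loop_a3a4[nrow(coords$loop_a3a4), ]
  coords$a4 <- ca_helix(length(seg$a4), origin = p + c(0, 0, -1),
                        axis = c(0.64, 0, -0.77))
  p <- coords$a4[nrow(coords$a4), ]
  coords$loop_a4a5 <- straight_trace(length(seg$loop_a4a5), p,
                                     c(0.8, 0.3, -0.52))
  p <- coords$loop_a4a5[nrow(coords$loop_a4a5), ]
  coords$a5 <- ca_helix(length(seg$a5), origin = p + c(1, 0, 0),
                        axis = c(0.94, 0, -0.34))
  p <- coords$a5[nrow(coords$a5), ]
  coords$tail <- straight_trace(length(seg$tail), p, c(1, 0.5, 0))

  xyz <- do.call(rbind, coords)
  new_monomer(tibble(resno = unlist(seg, use.names = FALSE),
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
              segments = seg)
}

new_monomer <- function(atoms, segments = list()) {
  stopifnot(all(c("resno", "x", "y", "z") %in% names(atoms)))
  if (any(diff(atoms$resno) <= 0)) {
    abort("residue numbers must be strictly increasing.")
  }
  structure(list(atoms = as_tibble(atoms), segments = segments),
            class = "monomer_model")
}

#' @export
print.monomer_model <- function(x, ...) {
  cat(sprintf("<monomer_model> %d residues (%d-%d), %d segments\n",
              nrow(x$atoms), min(x$atoms$resno), max(x$atoms$resno),
              length(x$segments)))
  invisible(x)
}

monomer_xyz <- function(model, resno = NULL) {
  atoms <- model$atoms
  if (!is.null(resno)) {
    idx <- match(resno, atoms$resno)
    if (anyNA(idx)) {
      abort(sprintf("residues missing a C-alpha: %s",
                    paste(resno[is.na(idx)], collapse = ", ")))
    }
    atoms <- atoms[idx, ]
  }
  as.matrix(atoms[, c("x", "y", "z")])
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg2rad(angle_deg)
  ca <- cos(a); sa <- sin(a)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) * ca + sa * K + (1 - ca) * (u %o% u)
}

#' Rigidly rotate the segment distal to a hinge
#'
#' Residues up to and including `hinge` stay in place; all residues after
#' the hinge are rotated by `angle` degrees about an axis passing through
#' the hinge C-alpha. This is the forward model against which hinge-angle
#' recovery is tested.
#'
#' @param monomer A `monomer_model`.
#' @param hinge Residue number of the hinge pivot.
#' @param angle Rotation angle in degrees.
#' @param axis Rotation axis, either a length-3 numeric vector or `"auto"`
#'   (default), which picks a unit vector perpendicular to the distal
#'   segment's principal axis so that the full rotation angle is expressed
#'   as an axis displacement.
#' @return A new `monomer_model` with the distal segment rotated.
#' @export
perturb_monomer <- function(monomer, hinge, angle, axis = "auto") {
  stopifnot(inherits(monomer, "monomer_model"))
  atoms <- monomer$atoms
  if (!hinge %in% atoms$resno) abort("`hinge` is not a residue of the model.")
  distal <- atoms$resno > hinge
  if (!any(distal)) {
    abort("hinge at the terminal residue: the distal segment is empty.")
  }
  pivot <- as.numeric(atoms[atoms$resno == hinge, c("x", "y", "z")])
  if (identical(axis, "auto")) {
    a <- principal_axis(as.matrix(atoms[distal, c("x", "y", "z")]))
    ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    axis <- c(a[2] * ref[3] - a[3] * ref[2],
              a[3] * ref[1] - a[1] * ref[3],
              a[1] * ref[2] - a[2] * ref[1])
  }
  R <- rotation_about_axis(axis, angle)
  xyz <- as.matrix(atoms[distal, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, pivot) %*% t(R)
  xyz <- sweep(xyz, 2, pivot, "+")
  atoms[distal, c("x", "y", "z")] <- as.data.frame(xyz)
  new_monomer(atoms, monomer$segments)
}

# first principal component of a point cloud, oriented start -> end
principal_axis <- function(xyz) {
  if (nrow(xyz) < 4) abort("need at least 4 points for a stable axis.")
  centred <- sweep(xyz, 2, colMeans(xyz))
  v <- svd(centred, nu = 0, nv = 1)$v[, 1]
  if (sum(v * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) v <- -v
  v
}
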