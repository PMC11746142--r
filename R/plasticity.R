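#' Least-squares superposition of two C-alpha sets
#'
#' Solves the orthogonal Procrustes problem by singular value decomposition
#' (the Kabsch algorithm): the proper rotation (determinant +1) and
#' translation minimizing the RMSD of the paired query points onto the
#' reference.
#'
#' @param query,reference `n x 3` coordinate matrices (or `monomer_model`s,
#'   in which case `resno` selects the paired residues).
#' @param resno Optional residue numbers used when models are supplied.
#'
#' @return An object of class `superposition`: list with `rotation` (3x3),
#'   `translation` (length 3), `rmsd`, `angle_deg` (rotation magnitude) and
#'   `transform`, a function mapping an `n x 3` matrix through the fitted
#'   rigid transform.
#' @examples
#' m <- toy_monomer()
#' superpose(m, m)$rmsd  # 0
#' @export
superpose <- function(query, reference, resno = NULL) {
  q <- if (inherits(query, "monomer_model")) monomer_xyz(query, resno) else
    as.matrix(query)
  r <- if (inherits(reference, "monomer_model")) {
    monomer_xyz(reference, resno)
  } else {
    as.matrix(reference)
  }
  if (!identical(dim(q), dim(r))) {
    abort("query and reference must contain the same number of paired points.")
  }
  if (nrow(q) < 3) abort("need at least 3 paired points.")
  cq <- colMeans(q)
  cr <- colMeans(r)
  H <- crossprod(sweep(q, 2, cq), sweep(r, 2, cr))
  s <- svd(H)
  if (s$d[2] < 1e-8 * max(s$d[1], 1)) {
    abort("degenerate (collinear) point set: superposition is not unique.")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transform <- function(xyz) {
    sweep(sweep(as.matrix(xyz), 2, cq) %*% t(R), 2, cr, "+")
  }
  moved <- transform(q)
  rmsd <- sqrt(mean(rowSums((moved - r)^2)))
  tr <- (sum(diag(R)) - 1) / 2
  structure(list(rotation = R, translation = cr - as.vector(R %*% cq),
                 rmsd = rmsd,
                 angle_deg = rad2deg(acos(max(min(tr, 1), -1))),
                 transform = transform),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rotation %.2f deg, RMSD %.4f A\n",
              x$angle_deg, x$rmsd))
  invisible(x)
}

#' Hinge definitions
#'
#' Default residue ranges for the three hinge regions of the PspA-like
#' fold: hinge 1 at the alpha2-alpha3 transition (pivot residues 128-133),
#' hinge 2 at the alpha3/alpha4 loop (156-165) and hinge 3 at the
#' alpha4/alpha5 loop (187-189). Each hinge carries the residue ranges of
#' its two flanking helical segments (`proximal` before the pivot,
#' `distal` after), between which the opening angle is measured. The exact
#' helix boundaries are approximations and can be overridden.
#'
#' @param hinge1,hinge2,hinge3 Lists with `pivot`, `proximal` and `distal`
#'   residue vectors.
#' @return A named list of hinge definitions.
#' @export
hinge_definitions <- function(hinge1 = list(pivot = 128:133,
                                            proximal = 106:127,
                                            distal = 134:155),
                              hinge2 = list(pivot = 156:165,
                                            proximal = 134:155,
                                            distal = 166:186),
                              hinge3 = list(pivot = 187:189,
                                            proximal = 166:186,
                                            distal = 190:217)) {
  hinges <- list(hinge1 = hinge1, hinge2 = hinge2, hinge3 = hinge3)
  for (h in hinges) {
    if (length(intersect(h$pivot, h$distal)) > 0 ||
        max(h$pivot) > min(h$distal)) {
      abort("hinge pivot and distal ranges must be disjoint, distal after pivot.")
    }
  }
  hinges
}

#' Hinge displacement angles between two conformers
#'
#' Superposes the query monomer on the reference over the hairpin residue
#' range, then, for each hinge, fits principal axes to the C-alpha traces
#' of the two segments flanking the hinge and measures the opening angle
#' between the proximal and distal axes in each model. The displacement
#' angle is the change of that opening angle, query minus reference, in
#' degrees. Measuring the angle between flanking segments (rather than in
#' the global frame) makes the three hinges independent: a rotation
#' applied at one hinge leaves the displacement angles of the downstream
#' hinges unchanged, and the sign is intrinsic — `hinge_angles(q, r)`
#' equals `-hinge_angles(r, q)`. A positive displacement opens the hinge.
#'
#' @param query,reference `monomer_model`s containing the hairpin and all
#'   hinge ranges.
#' @param hinges A list of hinge definitions, see [hinge_definitions()].
#' @param hairpin_range Residue range used for the superposition (default
#'   22:127, the alpha1/alpha2+3 hairpin core).
#'
#' @return A tibble with columns `hinge`, `angle_deg`, `opening_query_deg`,
#'   `opening_reference_deg`, `rmsd_hairpin_A`.
#' @export
hinge_angles <- function(query, reference, hinges = hinge_definitions(),
                         hairpin_range = 22:127) {
  stopifnot(inherits(query, "monomer_model"),
            inherits(reference, "monomer_model"))
  fit <- superpose(query, reference, resno = hairpin_range)

  cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
  # hinge-plane normal and axis pair of one model
  hinge_axes <- function(model, h, transform = identity) {
    ax_p <- principal_axis(transform(monomer_xyz(model, h$proximal)))
    ax_d <- principal_axis(transform(monomer_xyz(model, h$distal)))
    list(p = ax_p, d = ax_d, cr = cross3(ax_p, ax_d))
  }
  rows <- purrr::imap(hinges, function(h, name) {
    if (length(h$distal) < 4 || length(h$proximal) < 4) {
      abort(sprintf("%s: flanking ranges need at least 4 residues.", name))
    }
    ar <- hinge_axes(reference, h)
    aq <- hinge_axes(query, h, fit$transform)
    # opening angles signed against the shared (bisector) hinge-plane
    # normal, symmetric in the two models so the displacement is exactly
    # antisymmetric; a hinge closing through zero goes negative rather
    # than folding back (degenerate only for near-opposite hinge planes)
    n_hat <- ar$cr + aq$cr
    n_hat <- n_hat / sqrt(sum(n_hat^2))
    theta_r <- rad2deg(atan2(sum(ar$cr * n_hat), sum(ar$p * ar$d)))
    theta_q <- rad2deg(atan2(sum(aq$cr * n_hat), sum(aq$p * aq$d)))
    tibble(hinge = name, angle_deg = theta_q - theta_r,
           opening_query_deg = theta_q, opening_reference_deg = theta_r,
           rmsd_hairpin_A = fit$rmsd)
  })
  dplyr::bind_rows(rows)
}

#' End-to-end C-alpha distance
#'
#' Euclidean distance between the C-alpha atoms of two residues; defaults
#' to residues 82 and 187, the bow-tension descriptor of the PspA monomer.
#'
#' @param model A `monomer_model`.
#' @param residue_a,residue_b Residue numbers.
#' @return Distance in Angstrom.
#' @export
end_to_end <- function(model, residue_a = 82, residue_b = 187) {
  xyz <- monomer_xyz(model, c(residue_a, residue_b))
  sqrt(sum((xyz[1, ] - xyz[2, ])^2))
}

#' Fixed versus switching inter-subunit contacts across rod classes
#'
#' For each residue pair (residue i in a reference chain, residue j in the
#' chain at a given chain offset) the C-alpha distance is measured in every
#' model of a diameter-ordered series. Distance changes are taken relative
#' to the first (smallest-diameter) class and their standard deviation is
#' the flexibility measure: pairs with s.d. below the threshold keep fixed
#' contacts, pairs above it switch contacts as the diameter grows.
#'
#' @param models A named list of `assembly_model`s ordered by increasing
#'   rod diameter; names label the classes.
#' @param pairs A data frame with columns `residue_i`, `chain_offset`,
#'   `residue_j`.
#' @param reference_chain Index of the reference chain j0 in each model;
#'   default picks the middle chain so offsets in both directions resolve.
#' @param threshold Classification threshold in Angstrom (default 1).
#' @param sd_type `"population"` (default) or `"sample"`.
#'
#' @return A tibble with one row per pair: the pair definition, `sd_A`,
#'   `class` (`"fixed"`/`"switching"`) and a list-column `series` holding
#'   the per-class distances and changes.
#' @export
contact_series <- function(models, pairs, reference_chain = NULL,
                           threshold = 1, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(models) >= 2, is.data.frame(pairs))
  if (!all(c("residue_i", "chain_offset", "residue_j") %in% names(pairs))) {
    abort("`pairs` needs columns residue_i, chain_offset, residue_j.")
  }
  labels <- names(models) %||% as.character(seq_along(models))

  pair_rows <- purrr::pmap(pairs, function(residue_i, chain_offset,
                                           residue_j, ...) {
    d <- purrr::map2_dbl(models, labels, function(m, lab) {
      j0 <- reference_chain %||% ceiling(length(m$chains) / 2)
      jk <- j0 + chain_offset
      if (jk < 1 || jk > length(m$chains)) {
        abort(sprintf(
          "model `%s`: chain offset %+d from reference chain %d is out of range.",
          lab, chain_offset, j0))
      }
      a <- monomer_xyz(chain_monomer(m, j0), residue_i)
      b <- monomer_xyz(chain_monomer(m, jk), residue_j)
      sqrt(sum((a - b)^2))
    })
    changes <- d - d[1]
    s <- if (sd_type == "population") {
      sqrt(mean((changes - mean(changes))^2))
    } else {
      sd(changes)
    }
    tibble(residue_i = residue_i, chain_offset = chain_offset,
           residue_j = residue_j, sd_A = s,
           class = if (s < threshold) "fixed" else "switching",
           series = list(tibble(class_label = labels, distance_A = d,
                                change_A = changes)))
  })
  dplyr::bind_rows(pair_rows)
}

#' Helical extent of a segment
#'
#' Scans a residue range for stretches with alpha-helical local geometry:
#' residue i is helical when the C-alpha(i) to C-alpha(i+4) distance lies
#' inside the helical window (default 5.9-6.7 Angstrom, the i,i+4 spacing
#' of an ideal alpha-helix). Maximal contiguous runs are reported; in the
#' PspA series the run covering alpha3-alpha4 grows as the connecting loop
#' vanishes in wider rods.
#'
#' @param model A `monomer_model`.
#' @param segment Residue range to scan (>= 7 residues).
#' @param window Helical i,i+4 distance window in Angstrom.
#' @return A tibble of runs with columns `start_resno`, `end_resno`,
#'   `n_res`.
#' @export
helix_extent <- function(model, segment, window = c(5.9, 6.7)) {
  if (length(segment) < 7) abort("`segment` must contain at least 7 residues.")
  xyz <- monomer_xyz(model, segment)
  n <- length(segment)
  i <- 1:(n - 4)
  d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[i + 4, , drop = FALSE])^2))
  helical <- d >= window[1] & d <= window[2]
  if (!any(helical)) {
    return(tibble(start_resno = integer(), end_resno = integer(),
                  n_res = integer()))
  }
  r <- rle(helical)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble(start_resno = segment[starts[keep]],
         end_resno = segment[pmin(ends[keep] + 4, n)],
         n_res = segment[pmin(ends[keep] + 4, n)] -
           segment[starts[keep]] + 1L)
}
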