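test_that("superposition solves orthogonal Procrustes exactly", {
  m <- toy_monomer()
  xyz <- rodmorph:::monomer_xyz(m)
  s <- superpose(m, m)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)

  # constructed rotation is recovered to machine precision
  R <- rodmorph:::rotation_about_axis(c(1, 2, 0.5), 37)
  moved <- xyz %*% t(R) + matrix(c(3, -4, 8), nrow(xyz), 3, byrow = TRUE)
  s2 <- superpose(moved, xyz)
  expect_equal(s2$angle_deg, 37, tolerance = 1e-6)
  expect_equal(s2$rmsd, 0, tolerance = 1e-8)

  expect_error(superpose(xyz[1:5, ], xyz[1:6, ]), "same number")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superpose(line, line), "collinear")
})

test_that("only proper rotations are returned for reflected sets", {
  m <- toy_monomer()
  xyz <- rodmorph:::monomer_xyz(m)
  mirrored <- xyz %*% diag(c(-1, 1, 1))
  s <- superpose(mirrored, xyz)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_gt(s$rmsd, 1)
})

test_that("fitted RMSD beats random rigid placements", {
  m <- toy_monomer()
  xyz <- rodmorph:::monomer_xyz(m)[seq(1, 200, by = 10), ]
  q <- xyz + matrix(rnorm(nrow(xyz) * 3, sd = 0.5), ncol = 3)
  best <- superpose(q, xyz)$rmsd
  withr::with_seed(2, {
    for (i in 1:1000) {
      R <- rodmorph:::rotation_about_axis(rnorm(3), runif(1, 0, 360))
      trial <- sweep(q %*% t(R), 2, rnorm(3, sd = 5), "+")
      expect_gte(sqrt(mean(rowSums((trial - xyz)^2))), best - 1e-9)
    }
  })
})

test_that("injected hinge rotations are recovered within half a degree", {
  m <- toy_monomer()
  expect_equal(hinge_angles(m, m)$angle_deg, rep(0, 3), tolerance = 1e-9)
  for (a in c(-45, -20, -5, 5, 20, 45)) {
    q <- perturb_monomer(m, 160, a)
    ha <- hinge_angles(q, m)
    expect_equal(abs(ha$angle_deg[ha$hinge == "hinge2"]), abs(a),
                 tolerance = 0.5)
    # the other hinges are untouched: flanking-segment angles are local
    expect_equal(ha$angle_deg[ha$hinge == "hinge1"], 0, tolerance = 0.1)
    expect_equal(ha$angle_deg[ha$hinge == "hinge3"], 0, tolerance = 0.1)
  }
  # a hinge-3 rotation shows up only at hinge 3
  q3 <- perturb_monomer(m, 189, 15)
  ha3 <- hinge_angles(q3, m)
  expect_equal(abs(ha3$angle_deg[3]), 15, tolerance = 0.5)
  expect_equal(ha3$angle_deg[1:2], c(0, 0), tolerance = 0.1)
})

test_that("coaxial hinge rotations compose additively", {
  m <- toy_monomer()
  q1 <- perturb_monomer(m, 160, 10, axis = c(0, 1, 0))
  q2 <- perturb_monomer(q1, 160, 10, axis = c(0, 1, 0))
  a1 <- hinge_angles(q1, m)$angle_deg[2]
  a2 <- hinge_angles(q2, m)$angle_deg[2]
  expect_equal(a2, 2 * a1, tolerance = 0.5)
  expect_equal(abs(a2), 20, tolerance = 0.5)
})

test_that("hinge displacement is antisymmetric in query and reference", {
  m <- toy_monomer()
  q <- perturb_monomer(m, 160, 20, axis = c(0, 1, 0))
  fwd <- hinge_angles(q, m)$angle_deg
  rev <- hinge_angles(m, q)$angle_deg
  expect_equal(fwd, -rev, tolerance = 1e-6)
})

test_that("end-to-end distance behaves like a bow under tension", {
  m <- toy_monomer()
  two <- rodmorph:::new_monomer(
    tibble::tibble(resno = c(82, 187), x = c(0, 3), y = c(0, 4), z = 0))
  expect_equal(end_to_end(two), 5)
  # invariant under rigid motion
  R <- rodmorph:::rotation_about_axis(c(0, 1, 1), 63)
  xyz <- rodmorph:::monomer_xyz(m) %*% t(R) + 11
  rot <- rodmorph:::new_monomer(
    tibble::tibble(resno = m$atoms$resno, x = xyz[, 1], y = xyz[, 2],
                   z = xyz[, 3]))
  expect_equal(end_to_end(rot), end_to_end(m), tolerance = 1e-9)
  # straightening the bent fixture at hinge 2 pulls 82 and 187 apart
  d <- sapply(c(-40, -30, -20, -10, 0), function(a)
    end_to_end(perturb_monomer(m, 160, a, axis = c(0, 1, 0))))
  expect_true(all(diff(d) > 0))
  expect_error(end_to_end(m, 82, 999), "missing")
})

test_that("contact series classifies fixed and switching pairs", {
  m <- toy_monomer()
  asm <- generate_helical_assembly(m, helical_symmetry(1, 2.52, 130.2),
                                   n_steps = 5, radius = 100)
  pairs <- tibble::tibble(residue_i = c(44, 126),
                          chain_offset = c(1, 1),
                          residue_j = c(55, 170))

  # identical models: all changes zero, everything fixed
  cs <- contact_series(list(a = asm, b = asm, c = asm), pairs)
  expect_equal(cs$sd_A, c(0, 0))
  expect_identical(cs$class, c("fixed", "fixed"))

  # constant offset in every class: s.d. of changes is 0 -> still fixed
  # (the s.d. measures variance of change, not its magnitude)
  wider <- generate_helical_assembly(m, helical_symmetry(1, 2.52, 130.2),
                                     n_steps = 5, radius = 103)
  cs2 <- contact_series(list(a = wider, b = wider, c = wider), pairs)
  expect_equal(cs2$sd_A, c(0, 0))
  expect_identical(cs2$class, c("fixed", "fixed"))

  # alternating geometry across classes: s.d. above 1 A -> switching
  models <- list(a = asm, b = wider, c = asm, d = wider)
  cs3 <- contact_series(models, pairs)
  d <- cs3$series[[1]]$distance_A
  changes <- d - d[1]
  expect_equal(cs3$sd_A[1], sqrt(mean((changes - mean(changes))^2)))
  # sweeping the threshold moves pairs monotonically switching -> fixed
  labels <- sapply(c(0.001, 0.1, 1, 10, 1e4), function(th)
    sum(contact_series(models, pairs, threshold = th)$class == "fixed"))
  expect_true(all(diff(labels) >= 0))

  # distances are invariant under a rigid transform of one whole model
  R <- rodmorph:::rotation_about_axis(c(1, 0, 2), 30)
  moved <- asm
  moved$chains <- lapply(asm$chains, function(ch) {
    xyz <- as.matrix(ch[, c("x", "y", "z")]) %*% t(R) + 5
    tibble::tibble(resno = ch$resno, x = xyz[, 1], y = xyz[, 2],
                   z = xyz[, 3])
  })
  cs4 <- contact_series(list(a = moved, b = wider, c = asm, d = wider),
                        pairs)
  expect_equal(cs4$series[[1]]$distance_A, cs3$series[[1]]$distance_A,
               tolerance = 1e-9)

  expect_error(contact_series(list(a = asm, b = asm),
                              tibble::tibble(residue_i = 44,
                                             chain_offset = 50,
                                             residue_j = 55)),
               "out of range")
})

test_that("helix extent finds helical runs and excludes loops", {
  ideal <- rodmorph:::new_monomer(
    tibble::tibble(resno = 1:30,
                   x = ca_helix(30)[, 1], y = ca_helix(30)[, 2],
                   z = ca_helix(30)[, 3]))
  runs <- helix_extent(ideal, 1:30)
  expect_identical(nrow(runs), 1L)
  expect_identical(c(runs$start_resno, runs$end_resno), c(1L, 30L))

  extended <- rodmorph:::new_monomer(
    tibble::tibble(resno = 1:20, x = 3.8 * (1:20), y = 0, z = 0))
  expect_identical(nrow(helix_extent(extended, 1:20)), 0L)

  hlh <- helix_loop_helix()
  runs2 <- helix_extent(hlh, 1:30)
  expect_identical(nrow(runs2), 2L)
  # the loop interior (residues 14-17) belongs to no helical run
  covered <- unlist(purrr::map2(runs2$start_resno, runs2$end_resno, seq))
  expect_length(intersect(covered, 14:17), 0)

  expect_error(helix_extent(ideal, 1:5), "at least 7")
})

test_that("assemblies round-trip through PDB files", {
  m <- toy_monomer()
  asm <- generate_helical_assembly(m, helical_symmetry(2, 5.75, 34.4),
                                   n_steps = 30, radius = 100)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_assembly(asm, path)
  back <- load_model(path)
  expect_identical(length(back$chains), 60L)
  for (ch in c("A", "Q", "5")) {
    expect_equal(rodmorph:::monomer_xyz(chain_monomer(back, ch)),
                 rodmorph:::monomer_xyz(chain_monomer(asm, ch)),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(), empty)
  expect_error(load_model(empty))
})
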