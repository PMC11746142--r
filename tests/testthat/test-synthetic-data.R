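test_that("vesicle field generator handles the empty case", {
  f <- generate_vesicle_field(n_vesicles = 0, image_size = 128, seed = 1)
  expect_identical(nrow(f$truth), 0L)
  expect_true(all(f$mask == 0))
})

test_that("vesicle fields are reproducible from the seed", {
  a <- generate_vesicle_field(n_vesicles = 8, nested_fraction = 0.25,
                              noise_sigma = 0.1, seed = 17)
  b <- generate_vesicle_field(n_vesicles = 8, nested_fraction = 0.25,
                              noise_sigma = 0.1, seed = 17)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth, b$truth)
})

test_that("nested fraction is realized exactly by construction", {
  f <- generate_vesicle_field(n_vesicles = 30, nested_fraction = 0.5,
                              seed = 1)
  expect_identical(sum(!is.na(f$truth$parent)), 15L)
  # children fit inside their parents with the requested clearance range
  kids <- which(!is.na(f$truth$parent))
  expect_true(all(f$truth$enclosure_distance_A[kids] >= 50))
  expect_true(all(f$truth$enclosure_distance_A[kids] <= 85))
})

test_that("impossible packings fail with a placement error", {
  expect_error(
    generate_vesicle_field(n_vesicles = 60, image_size = 256,
                           max_retries = 20, seed = 1),
    "placement failure")
  expect_error(
    generate_vesicle_field(n_vesicles = 4, nested_fraction = 0.5,
                           radius_range_px = c(12, 14), seed = 1),
    "placement failure")
})

test_that("generated bilayer minima sit at the requested spacing", {
  # analytic check on the noiseless intensity along a radial ray
  f <- generate_vesicle_field(n_vesicles = 1, pixel_size = 1,
                              radius_range_px = c(60, 60),
                              bilayer_spacing_A = 31, image_size = 256,
                              margin_px = 30, seed = 3)
  tr <- f$truth
  ray_r <- seq(tr$radius_px - 25, tr$radius_px + 25, by = 0.05)
  cc <- round(tr$center_col)
  vals <- sapply(ray_r, function(r) {
    rr <- tr$center_row + r
    r0 <- floor(rr)
    f$intensity[r0, cc] * (1 - (rr - r0)) + f$intensity[r0 + 1, cc] * (rr - r0)
  })
  # deepest minimum on each side of the skeleton radius
  inner <- ray_r[ray_r < tr$radius_px][which.min(vals[ray_r < tr$radius_px])]
  outer <- ray_r[ray_r > tr$radius_px][which.min(vals[ray_r > tr$radius_px])]
  spacing <- (outer - inner) * f$pixel_size
  expect_equal(spacing, 31, tolerance = 0.5)
})

test_that("every truth vesicle is one closed mask component", {
  f <- generate_vesicle_field(n_vesicles = 12, nested_fraction = 0.25,
                              seed = 5)
  traces <- skeletonize(f$mask, f$pixel_size)
  closed <- select_closed(traces)
  expect_identical(length(closed), nrow(f$truth))
  expect_identical(attr(traces, "n_discarded"), 0L)
})

test_that("perturbed contours still yield valid closed components", {
  f <- generate_vesicle_field(n_vesicles = 6, contour_perturbation = 0.05,
                              seed = 8)
  closed <- select_closed(skeletonize(f$mask, f$pixel_size))
  expect_identical(length(closed), 6L)
  # perturbed perimeter exceeds the circle perimeter of the same radius
  expect_true(all(f$truth$perimeter_nm >=
                    2 * pi * f$truth$radius_px * f$pixel_size / 10 - 1e-6))
})

test_that("synthetic fields round-trip through TIFF/JSON", {
  f <- generate_vesicle_field(n_vesicles = 3, seed = 2, image_size = 400)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_field(f, dir)
  expect_true(all(file.exists(paths)))
  mask_back <- round(tiff::readTIFF(paths["mask"]))
  expect_equal(max(abs(mask_back - f$mask)), 0)
  truth_back <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth_back$pixel_size, f$pixel_size)
  expect_equal(nrow(truth_back$truth), 3)
})

test_that("toy monomer satisfies its structural contract", {
  m <- toy_monomer()
  expect_identical(nrow(m$atoms), 200L)
  expect_true(all(diff(m$atoms$resno) > 0))
  # segment ranges are disjoint
  all_res <- unlist(m$segments)
  expect_identical(anyDuplicated(all_res), 0L)
  # helical segments have alpha-helical i,i+4 geometry
  ext <- helix_extent(m, m$segments$a4)
  expect_identical(nrow(ext), 1L)
  expect_identical(ext$n_res, length(m$segments$a4))
})

test_that("perturb_monomer is the identity at zero and inverts exactly", {
  m <- toy_monomer()
  expect_equal(perturb_monomer(m, 160, 0)$atoms, m$atoms)
  q <- perturb_monomer(m, 160, 20, axis = c(0, 1, 0))
  back <- perturb_monomer(q, 160, -20, axis = c(0, 1, 0))
  expect_equal(max(abs(as.matrix(back$atoms[, 2:4]) -
                         as.matrix(m$atoms[, 2:4]))), 0,
               tolerance = 1e-9)
  # residues at or before the hinge never move
  expect_equal(q$atoms[q$atoms$resno <= 160, ],
               m$atoms[m$atoms$resno <= 160, ])
  expect_error(perturb_monomer(m, 221, 10), "terminal")
})

test_that("helical assemblies place chains on the screw lattice", {
  m <- toy_monomer()
  # identity case: one step of C1 is just the radially placed monomer
  one <- generate_helical_assembly(m, helical_symmetry(1, 2.52, 130.2),
                                   n_steps = 1, radius = 100)
  expect_identical(length(one$chains), 1L)
  expect_equal(mean(one$chains[[1]]$x), 100, tolerance = 1e-9)

  # the 200 A class builds 60 chains from 30 steps of C2
  asm <- generate_helical_assembly(m, helical_symmetry(2, 5.75, 34.4),
                                   n_steps = 30, radius = 100)
  expect_identical(length(asm$chains), 60L)
  # consecutive steps differ by one rise in z
  z_by_step <- tapply(asm$info$z_A, asm$info$step, unique)
  expect_equal(unname(diff(z_by_step))[1], 5.75)

  # rigid placement: intra-chain distances equal the monomer's
  d0 <- dist(as.matrix(m$atoms[, 2:4]))
  d1 <- dist(as.matrix(asm$chains[[37]][, c("x", "y", "z")]))
  expect_equal(max(abs(d0 - d1)), 0, tolerance = 1e-9)
})
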