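test_that("skeletonize reduces annuli to single closed traces", {
  expect_length(skeletonize(matrix(0L, 32, 32), 7), 0)
  one <- annulus_mask(140, c(70, 70), 50, 5)
  tr <- skeletonize(one, pixel_size = 7)
  expect_length(tr, 1)
  expect_true(tr[[1]]$closed)
  two <- matrix(0L, 140, 280)
  two[, 1:140] <- annulus_mask(140, c(70, 70), 50, 5)
  two[21:120, 161:260] <- annulus_mask(100, c(50, 50), 35, 5)
  expect_length(skeletonize(two, 7), 2)
  expect_error(skeletonize(matrix(0.5, 4, 4), 7), "binary")
})

test_that("open arcs and branched shapes are excluded from closed vesicles", {
  size <- 120
  d <- sqrt(outer((1:size - 60)^2, (1:size - 60)^2, "+"))
  half <- (abs(d - 40) <= 2.5 & outer(1:size - 60, rep(1, size)) > 0) * 1L
  tr <- skeletonize(half, 7)
  expect_length(tr, 1)
  expect_false(tr[[1]]$closed)
  expect_length(select_closed(tr), 0)

  # X-shaped branched component: junction pixels disqualify it
  x <- matrix(0L, 60, 60)
  for (i in 10:50) x[i, c(i, 60 - i)] <- 1L
  trx <- skeletonize(x, 7)
  expect_length(trx, 0)
  expect_identical(attr(trx, "n_discarded"), 1L)

  full <- annulus_mask(120, c(60, 60), 40, 5)
  expect_length(select_closed(skeletonize(full, 7)), 1)
})

test_that("perimeter follows the neighbour-distance sum in nm", {
  # hand-computable unit square at 10 A/px: 4 steps of 1 px = 4 nm
  sq <- rodmorph:::new_membrane_trace(
    cbind(c(5, 5, 6, 6), c(5, 6, 6, 5)), closed = TRUE, pixel_size = 10)
  expect_equal(vesicle_perimeter(sq), 4)
  open_tr <- rodmorph:::new_membrane_trace(
    cbind(c(5, 5, 6), c(5, 6, 6)), closed = FALSE, pixel_size = 10)
  expect_error(vesicle_perimeter(open_tr), "closed")

  # rasterized circle r = 100 px at 7 A/px: 2*pi*100*0.7 = 439.8 nm
  big <- annulus_mask(260, c(130, 130), 100, 7)
  tr <- select_closed(skeletonize(big, 7))[[1]]
  expect_equal(vesicle_perimeter(tr), 2 * pi * 100 * 0.7,
               tolerance = 0.05)

  # exact invariance under translation and 90-degree rotation of the mask
  small <- matrix(0L, 220, 220)
  small[31:150, 31:150] <- annulus_mask(120, c(60, 60), 40, 5)
  shifted <- matrix(0L, 220, 220)
  shifted[61:180, 71:190] <- annulus_mask(120, c(60, 60), 40, 5)
  p0 <- vesicle_perimeter(select_closed(skeletonize(small, 7))[[1]])
  p1 <- vesicle_perimeter(select_closed(skeletonize(shifted, 7))[[1]])
  p2 <- vesicle_perimeter(select_closed(skeletonize(
    t(small[nrow(small):1, ]), 7))[[1]])
  expect_identical(p0, p1)
  expect_identical(p0, p2)
})

test_that("nesting detection matches the analytic containment oracle", {
  # side-by-side circles: no relations
  m <- matrix(0L, 200, 400)
  m[, 1:200] <- annulus_mask(200, c(100, 100), 60, 5)
  m[41:160, 241:360] <- annulus_mask(120, c(60, 60), 40, 5)
  tr <- select_closed(skeletonize(m, 7))
  expect_identical(nrow(detect_nesting(tr)), 0L)

  # concentric circles r = 30 and 80
  cm <- annulus_mask(200, c(100, 100), 80, 5) |
    annulus_mask(200, c(100, 100), 30, 5)
  ctr <- select_closed(skeletonize(cm * 1L, 7))
  rel <- detect_nesting(ctr)
  expect_identical(nrow(rel), 1L)
  radii <- vapply(ctr, function(t)
    mean(sqrt(rowSums(sweep(t$points, 2, c(100, 100))^2))), numeric(1))
  expect_lt(radii[rel$inner], radii[rel$outer])

  # triple nesting r = 20/50/90: innermost enclosed by both others
  tm <- annulus_mask(220, c(110, 110), 90, 5) |
    annulus_mask(220, c(110, 110), 50, 5) |
    annulus_mask(220, c(110, 110), 20, 5)
  ttr <- select_closed(skeletonize(tm * 1L, 7))
  trel <- detect_nesting(ttr)
  expect_identical(nrow(trel), 3L)
  radii <- vapply(ttr, function(t)
    mean(sqrt(rowSums(sweep(t$points, 2, c(110, 110))^2))), numeric(1))
  innermost <- which.min(radii)
  expect_identical(sum(trel$inner == innermost), 2L)
})

test_that("enclosure distance matches the analytic ring separation", {
  cm <- (annulus_mask(200, c(100, 100), 80, 5) |
           annulus_mask(200, c(100, 100), 30, 5)) * 1L
  tr <- select_closed(skeletonize(cm, 7))
  radii <- vapply(tr, function(t)
    mean(sqrt(rowSums(sweep(t$points, 2, c(100, 100))^2))), numeric(1))
  inner <- tr[[which.min(radii)]]
  outer <- tr[[which.max(radii)]]
  expect_equal(enclosure_distance(inner, outer), 50 * 7, tolerance = 14)
  # invariance under rigid translation of both traces
  shift <- function(t) {
    t$points <- t$points + matrix(c(7, -3), nrow(t$points), 2, byrow = TRUE)
    t
  }
  expect_identical(enclosure_distance(shift(inner), shift(outer),
                                      check = FALSE),
                   enclosure_distance(inner, outer, check = FALSE))
  # unrelated vesicles are rejected
  expect_error(enclosure_distance(outer, inner), "not enclosed")
})

test_that("bilayer thickness is recovered from generated membranes", {
  # noiseless 31 A spacing at 1 A/px
  f <- generate_vesicle_field(n_vesicles = 1, pixel_size = 1,
                              radius_range_px = c(60, 60),
                              bilayer_spacing_A = 31, image_size = 300,
                              margin_px = 65, seed = 4)
  tr <- select_closed(skeletonize(f$mask, 1))[[1]]
  expect_equal(bilayer_thickness(tr, f$intensity), 31, tolerance = 0.5)

  # 38 A spacing with noise at 10 percent of the membrane contrast
  f2 <- generate_vesicle_field(n_vesicles = 1, pixel_size = 1,
                               radius_range_px = c(60, 60),
                               bilayer_spacing_A = 38, image_size = 300,
                               margin_px = 65, noise_sigma = 0.1, seed = 5)
  tr2 <- select_closed(skeletonize(f2$mask, 1))[[1]]
  expect_equal(bilayer_thickness(tr2, f2$intensity), 38, tolerance = 1)

  # a single dark ring has one minimum: thickness undefined
  size <- 200
  d <- sqrt(outer((1:size - 100)^2, (1:size - 100)^2, "+"))
  img <- -exp(-(d - 50)^2 / 2)
  ring <- (abs(d - 50) <= 2) * 1L
  tr3 <- select_closed(skeletonize(ring, 1))[[1]]
  expect_true(is.na(bilayer_thickness(tr3, img, half_width_A = 20)))

  # clearance violation is an error
  expect_error(bilayer_thickness(tr3, img, half_width_A = 80), "border")
})

test_that("field summaries follow the reporting conventions", {
  v <- tibble::tibble(perimeter_nm = 100, is_double_membrane = FALSE)
  s <- summarize_vesicles(v)
  expect_equal(s$mean_diameter_nm, 100 / pi)
  expect_equal(round(s$mean_diameter_nm), 32)
  expect_true(is.na(s$mean_thickness_A))
  expect_identical(s$n_thickness, 0L)

  v2 <- tibble::tibble(perimeter_nm = rep(100, 100),
                       is_double_membrane = rep(c(TRUE, FALSE), c(52, 48)))
  expect_equal(summarize_vesicles(v2)$double_membrane_fraction, 0.52)
  expect_error(summarize_vesicles(v2[0, ]), "at least one")
})

test_that("measured fields recover ground truth within tolerance", {
  f <- generate_vesicle_field(n_vesicles = 25, nested_fraction = 0.2,
                              seed = 21)
  v <- measure_vesicles(f$mask, f$pixel_size)
  expect_identical(nrow(v), nrow(f$truth))
  m <- match_truth(f$truth, v)
  expect_identical(anyDuplicated(m), 0L)
  expect_true(all(abs(v$perimeter_nm[m] / f$truth$perimeter_nm - 1) < 0.05))
  # nesting equals truth exactly
  expect_identical(v$is_double_membrane[m], !is.na(f$truth$parent))
  # enclosure distances within 2 px * pixel_size
  kids <- which(!is.na(f$truth$parent))
  expect_true(all(abs(v$enclosure_distance_A[m[kids]] -
                        f$truth$enclosure_distance_A[kids]) <=
                    2 * f$pixel_size))
  # nesting graph is acyclic by construction of the relation
  rel <- detect_nesting(attr(v, "traces"))
  expect_identical(nrow(dplyr::inner_join(rel, rel,
                                          by = c(inner = "outer",
                                                 outer = "inner"))), 0L)
})
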