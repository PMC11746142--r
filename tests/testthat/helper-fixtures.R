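# shared fixture builders: all fixtures are generated in code

# ideal annulus mask: ring of given mid-radius and full width (pixels)
annulus_mask <- function(size, center, radius, width = 5) {
  d <- sqrt(outer((seq_len(size) - center[1])^2,
                  (seq_len(size) - center[2])^2, "+"))
  (abs(d - radius) <= width / 2) * 1L
}

# match ground-truth vesicles to measured traces by centroid and radius
match_truth <- function(truth, measured) {
  traces <- attr(measured, "traces")
  cent <- t(vapply(traces, function(t) colMeans(t$points), numeric(2)))
  rad <- vapply(traces, function(t)
    mean(sqrt(rowSums(sweep(t$points, 2, colMeans(t$points))^2))),
    numeric(1))
  vapply(seq_len(nrow(truth)), function(i) {
    which.min(sqrt((cent[, 1] - truth$center_row[i])^2 +
                     (cent[, 2] - truth$center_col[i])^2) +
                abs(rad - truth$radius_px[i]))
  }, integer(1))
}

# two-sided permutation p-value for a difference in means (t-test oracle)
permutation_pvalue <- function(a, b, n_perm = 20000, seed = 42) {
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  withr::with_seed(seed, {
    stats <- replicate(n_perm, {
      idx <- sample.int(length(pooled), length(a))
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
    mean(stats >= obs - 1e-12)
  })
}

# helix-loop-helix C-alpha fixture for helix_extent
helix_loop_helix <- function() {
  xyz <- rbind(
    ca_helix(12, c(0, 0, 0), c(0, 0, 1)),
    rodmorph:::straight_trace(6, c(0, 0, 18), c(1, 0, 0)),
    ca_helix(12, c(26, 0, 18), c(0, 0, 1))
  )
  rodmorph:::new_monomer(
    tibble::tibble(resno = 1:30, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}
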