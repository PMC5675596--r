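# Filter kernels and intensity-profile generation / normalization.

test_that("LoG_xy kernel matches its closed form and zero structure", {
  R_xy <- 0.52; R_z <- 1.6
  expect_equal(log_xy_kernel(0, 0, 0, R_xy, R_z),
               4 / (pi * R_xy^4 * sqrt(pi) * R_z))
  # zero crossing of the polynomial at lateral radius R_xy, any dz
  for (dz in c(0, 0.5, 2))
    expect_equal(log_xy_kernel(R_xy, 0, dz, R_xy, R_z), 0)
  expect_equal(log_xy_kernel(R_xy / sqrt(2), R_xy / sqrt(2), 1, R_xy, R_z),
               0)
  # zero mean in-plane at fixed dz (quadrature over a wide grid)
  g <- seq(-6 * R_xy, 6 * R_xy, by = 0.01)
  K <- outer(g, g, function(x, y) log_xy_kernel(x, y, 0.7, R_xy, R_z))
  expect_lt(abs(sum(K) * 0.01^2), 1e-6)
})

test_that("Gaussian kernel is normalized and isotropic", {
  R <- 0.52
  expect_equal(gaussian_kernel(0, 0, 0, R), 1 / (pi^1.5 * R^3))
  g <- seq(-5 * R, 5 * R, by = 0.02)
  K <- array(0, c(length(g), length(g), length(g)))
  for (k in seq_along(g))
    K[, , k] <- outer(g, g, function(x, y) gaussian_kernel(x, y, g[k], R))
  expect_equal(sum(K) * 0.02^3, 1, tolerance = 1e-4)
  # isotropy: value depends only on the norm
  v <- c(0.3, 0.2, 0.1); nv <- sqrt(sum(v^2))
  expect_equal(gaussian_kernel(v[1], v[2], v[3], R),
               gaussian_kernel(nv, 0, 0, R))
})

test_that("profiles of a uniform stack reflect the kernel means", {
  st <- image_stack(array(100, c(48, 48, 24)), c(0.26, 0.26, 0.8))
  tr <- axon_trace(cbind(seq(4, 8, by = 0.26), 6.2, 9.6))
  g <- intensity_profile(st, tr, filter_spec("gaussian"))
  expect_equal(g$values, rep(100, length(g$values)), tolerance = 1e-3)
  lg <- intensity_profile(st, tr, filter_spec("log_xy_multiscale"))
  # zero-mean in-plane filter: response tiny relative to the intensity scale
  expect_lt(max(abs(lg$values)), 100 * 1e-3)
})

test_that("multi-scale LoG response dominates every single scale", {
  d <- demo_scene()
  ms <- intensity_profile(d$scene$stack, d$trace,
                          filter_spec("log_xy_multiscale", n_scales = 4))
  for (R in c(1.5, 2.0, 2.5, 3.0)) {
    single <- intensity_profile(
      d$scene$stack, d$trace,
      filter_spec("log_xy_multiscale", R_xy_range = c(R, R), n_scales = 1))
    expect_true(all(ms$values - single$values >= -1e-9),
                label = sprintf("scale %.1f below multiscale", R))
  }
})

test_that("normalization gives unit mean, scale invariance, exclusions", {
  p <- manual_profile(s = 0:2, v = c(2, 4, 6))
  expect_equal(normalize_profile(p)$values, c(0.5, 1, 1.5))
  # constant profile
  expect_equal(normalize_profile(manual_profile(0:3, rep(3, 4)))$values,
               rep(1, 4))
  # scale invariance
  p2 <- manual_profile(0:2, 17.3 * c(2, 4, 6))
  expect_equal(normalize_profile(p2)$values,
               normalize_profile(p)$values, tolerance = 1e-12)
  # excluded nodes do not contribute to the mean
  pe <- manual_profile(0:3, c(2, 4, 1000, 6), excluded = c(F, F, T, F))
  expect_equal(normalize_profile(pe)$values[c(1, 2, 4)], c(0.5, 1, 1.5))
  expect_error(normalize_profile(manual_profile(0:2, rep(0, 3))),
               "not normalizable")
})

test_that("global image rescaling leaves normalized profiles unchanged", {
  d <- demo_scene()
  st2 <- image_stack(2.5 * d$scene$stack$values, d$scene$stack$voxel_size)
  for (spec in list(filter_spec("log_xy_multiscale"),
                    filter_spec("gaussian"))) {
    p1 <- normalize_profile(intensity_profile(d$scene$stack, d$trace, spec))
    p2 <- normalize_profile(intensity_profile(st2, d$trace, spec))
    expect_equal(p2$values, p1$values, tolerance = 1e-9)
  }
})

test_that("a bouton blob produces a profile maximum at its arc position", {
  d <- demo_scene()
  prof <- normalize_profile(intensity_profile(
    d$scene$stack, d$trace, filter_spec("log_xy_multiscale")))
  # largest bouton: profile max within one node spacing of the blob
  big <- d$axon$boutons[which.max(d$axon$boutons$volume), ]
  near <- abs(prof$positions - big$s_um) < 1.5
  peak_pos <- prof$positions[near][which.max(prof$values[near])]
  expect_lt(abs(peak_pos - big$s_um), 0.1)
  # and it is a global neighborhood maximum, not a plateau artifact
  expect_gt(max(prof$values[near]), 1.5 * stats::median(prof$values))
})

test_that("baseline fixed filters work and normalize by the median", {
  st <- image_stack(array(50, c(32, 32, 12)), c(0.26, 0.26, 0.8))
  tr <- axon_trace(cbind(seq(2, 6, by = 0.26), 4.2, 4.8))
  for (kind in c("mean_fixed", "median_fixed")) {
    p <- intensity_profile(st, tr, filter_spec(kind, window = 3L))
    expect_equal(p$values, rep(50, length(p$values)))
    expect_equal(normalize_profile(p)$values, rep(1, length(p$values)))
  }
})
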