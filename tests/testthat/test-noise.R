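# Measurement-noise model: LM-bouton probability, event probabilities,
# alpha estimation and standardized differences.

test_that("p_bouton reproduces the CLEM reference probabilities", {
  m <- noise_model(alpha = 0.24, w_threshold = 2.0)
  clem <- clem_boutons()
  # rows with a measured weight, excluding the two with documented
  # print/evaluation discrepancies (boutons 7 and 19)
  rows <- clem[!is.na(clem$weight) & !clem$bouton_id %in% c(7, 19), ]
  expect_equal(round(p_bouton(rows$weight, m), 2), rows$p_bouton,
               tolerance = 1e-9)
  # the worked single-value example
  expect_equal(round(p_bouton(1.5, m), 2), 0.12)
  # threshold weight sits exactly at one half
  expect_equal(p_bouton(2.0, m), 0.5)
  # continuous limit at zero
  expect_equal(p_bouton(0, m), 0)
})

test_that("p_bouton is monotone in the weight above a small floor", {
  m <- noise_model()
  w <- seq(0.01, 20, by = 0.01)
  p <- p_bouton(w, m)
  expect_true(all(diff(p[w > 0.5]) > -1e-15))
  expect_lt(p_bouton(0.5, m), 0.05)
  expect_gt(p_bouton(10, m), 0.999)
})

test_that("event probabilities satisfy their algebraic identities", {
  m <- noise_model()
  set.seed(42)
  wi <- runif(200, 0.2, 12); wf <- runif(200, 0.2, 12)
  ev <- event_probabilities(wi, wf, m)
  p_i <- p_bouton(wi, m); p_f <- p_bouton(wf, m)
  # total mass identity: everything except "absent in both sessions"
  expect_equal(ev$added + ev$eliminated + ev$potentiated + ev$depressed,
               1 - (1 - p_i) * (1 - p_f), tolerance = 1e-12)
  # potentiation/depression mirror symmetry
  ev_rev <- event_probabilities(wf, wi, m)
  expect_equal(ev$potentiated, ev_rev$depressed, tolerance = 1e-15)
  # equal weights split the change mass evenly
  ev_eq <- event_probabilities(wi, wi, m)
  expect_equal(ev_eq$potentiated, 0.5 * p_i^2, tolerance = 1e-12)
  expect_equal(ev_eq$depressed, ev_eq$potentiated)
  # a large jump from sub- to supra-threshold is almost surely an addition
  expect_gt(event_probabilities(0.5, 10, m)$added, 0.95)
})

test_that("alpha is recovered from pairs simulated under the model", {
  w0 <- exp(runif(10000, log(1), log(14)))
  set.seed(123)
  w0 <- exp(runif(10000, log(1), log(14)))
  w <- simulate_weight_pairs(w0, alpha = 0.24, n_sessions = 2, seed = 123)
  fit <- estimate_alpha(w[, 1], w[, 2], bins = 8, n_boot = 100, seed = 1)
  expect_gt(fit$alpha, 0.21)
  expect_lt(fit$alpha, 0.27)
  expect_gt(fit$alpha_sd, 0)
  expect_lt(fit$alpha_sd, 0.05)
  expect_equal(nrow(fit$bins), 8L)
  expect_equal(unname(coef(fit)["alpha"]), fit$alpha)
})

test_that("identical pairs give zero alpha; scaling diffs scales alpha", {
  w1 <- seq(1, 10, length.out = 200)
  expect_equal(estimate_alpha(w1, w1, bins = 4, n_boot = 0)$alpha, 0)
  set.seed(7)
  d <- rnorm(5000, sd = 0.3)
  w <- 4 + abs(rnorm(5000, sd = 2))
  a1 <- estimate_alpha(w + d / 2, w - d / 2, bins = 6, n_boot = 0)$alpha
  a2 <- estimate_alpha(w + d, w - d, bins = 6, n_boot = 0)$alpha
  expect_equal(a2 / a1, 4, tolerance = 0.05)
})

test_that("degenerate binning is reported as an error", {
  w <- c(1, 1.1, 1.2, 5, 5.1)
  expect_error(estimate_alpha(w, w + 0.1, bins = 2, n_boot = 0),
               "degenerate|fewer")
})

test_that("standardized differences behave like standard normal draws", {
  set.seed(99)
  w0 <- exp(runif(2000, log(1), log(14)))
  w <- simulate_weight_pairs(w0, alpha = 0.24, n_sessions = 2, seed = 99)
  z <- standardize_diffs(w[, 1], w[, 2], alpha = 0.24)
  expect_equal(stats::sd(z), 1, tolerance = 0.1)
  expect_gt(attr(z, "ks_p"), 0.01)
  # zero differences standardize to exactly zero
  z0 <- standardize_diffs(w[, 1], w[, 1], alpha = 0.24)
  expect_true(all(z0 == 0))
  # misspecified alpha (4x too small) doubles the standardized spread
  z4 <- standardize_diffs(w[, 1], w[, 2], alpha = 0.06)
  expect_equal(stats::sd(z4), 2, tolerance = 0.2)
})

test_that("simulated weight tables are deterministic and truncated", {
  w0 <- c(0.02, 1, 5)
  a <- simulate_weight_pairs(w0, 0.24, 3, seed = 5)
  b <- simulate_weight_pairs(w0, 0.24, 3, seed = 5)
  expect_identical(a, b)
  expect_true(all(a >= 0.01))
  # vanishing noise returns the true weights
  tiny <- simulate_weight_pairs(c(1, 4, 9), alpha = 1e-12, 2, seed = 1)
  expect_equal(tiny, matrix(c(1, 4, 9), 3, 2), tolerance = 1e-4)
  # variance of session differences matches var(dw) = alpha <w>
  big <- simulate_weight_pairs(rep(4, 1e5), 0.24, 2, seed = 2)
  expect_equal(stats::var(big[, 1] - big[, 2]), 0.96, tolerance = 0.03)
})
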