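# Constrained Gaussian peak decomposition, bouton and shaft intensities.

test_that("a flat unit profile yields no foreground and a unit background", {
  s <- seq(0, 50, by = 0.25)
  fit <- fit_peaks(manual_profile(s, rep(1, length(s)), normalized = TRUE))
  expect_equal(nrow(fit$foreground), 0L)
  expect_equal(nrow(fit$background), ceiling(50 / 25))
  expect_equal(unname(predict(fit, c(10, 25, 40))), rep(1, 3),
               tolerance = 0.1)
})

test_that("a single Gaussian bump is recovered with tight parameters", {
  s <- seq(0, 50, by = 0.25)
  y <- 1 + 3 * exp(-(s - 25)^2 / (2 * 1^2))
  fit <- fit_peaks(manual_profile(s, y, normalized = TRUE))
  expect_equal(nrow(fit$foreground), 1L)
  expect_lt(abs(fit$foreground$a - 3), 0.15)
  expect_lt(abs(fit$foreground$mu - 25), 0.1)
  expect_lt(abs(fit$foreground$sigma - 1), 0.15)
  # model methods are consistent
  expect_equal(fitted(fit), predict(fit))
  expect_equal(residuals(fit), y - fitted(fit))
  expect_lt(sum(residuals(fit)^2), 1)
  cf <- coef(fit)
  expect_setequal(unique(cf$kind), c("foreground", "background"))
})

test_that("two bumps closer than the merge distance end as one peak", {
  s <- seq(0, 30, by = 0.1)
  y <- 1 + 2 * exp(-(s - 14.75)^2 / (2 * 0.6^2)) +
    2 * exp(-(s - 15.25)^2 / (2 * 0.6^2))
  fit <- fit_peaks(manual_profile(s, y, normalized = TRUE))
  expect_equal(nrow(fit$foreground), 1L)
  expect_lt(abs(fit$foreground$mu - 15), 0.25)
})

test_that("well-separated bumps survive as distinct peaks", {
  s <- seq(0, 40, by = 0.1)
  mus <- c(8, 16, 25, 33)
  y <- rep(1, length(s))
  for (m in mus) y <- y + 2.5 * exp(-(s - m)^2 / (2 * 0.8^2))
  fit <- fit_peaks(manual_profile(s, y, normalized = TRUE))
  expect_equal(nrow(fit$foreground), 4L)
  expect_equal(sort(fit$foreground$mu), mus, tolerance = 0.1)
})

test_that("foreground widths honor their constraint bounds", {
  s <- seq(0, 30, by = 0.1)
  # a very narrow spike: fitted width must be clipped at the lower bound
  y <- 1 + 3 * exp(-(s - 15)^2 / (2 * 0.2^2))
  fit <- fit_peaks(manual_profile(s, y, normalized = TRUE))
  expect_true(all(fit$foreground$sigma >= 0.5 - 1e-9))
  expect_true(all(fit$foreground$sigma <= 2 + 1e-9))
  expect_true(all(fit$background$sigma >= 20 - 1e-9))
})

test_that("bouton intensity follows the amplitude-plus-background formula", {
  fg <- data.frame(a = c(3, 2.5), mu = c(10, 30), sigma = c(1, 1))
  # near-flat background of amplitude 1
  bg_flat <- data.frame(a = 1, mu = 25, sigma = 1e6)
  m <- manual_peak_fit(fg, bg_flat)
  expect_equal(bouton_intensity(m, 1), 4.0, tolerance = 1e-6)
  # zero background amplitude
  m0 <- manual_peak_fit(fg, data.frame(a = 0, mu = 25, sigma = 30))
  expect_equal(bouton_intensity(m0, 2), 2.5)
  # background centered exactly at the peak: exponent is zero
  mc <- manual_peak_fit(data.frame(a = 3, mu = 25, sigma = 1),
                        data.frame(a = 1, mu = 25, sigma = 20))
  expect_equal(bouton_intensity(mc, 1), 4.0)
})

test_that("shaft intensity averages the fitted background", {
  bg <- data.frame(a = 0.8, mu = 25, sigma = 1e6)
  expect_equal(shaft_intensity(manual_peak_fit(data.frame(a = numeric(0),
                                                          mu = numeric(0),
                                                          sigma = numeric(0)),
                                               bg)), 0.8, tolerance = 1e-6)
  # linearity: two identical backgrounds double the shaft
  bg2 <- rbind(bg, bg)
  expect_equal(shaft_intensity(manual_peak_fit(data.frame(a = numeric(0),
                                                          mu = numeric(0),
                                                          sigma = numeric(0)),
                                               bg2)), 1.6, tolerance = 1e-6)
  expect_error(shaft_intensity(manual_peak_fit(
    data.frame(a = numeric(0), mu = numeric(0), sigma = numeric(0)),
    data.frame(a = 0, mu = 10, sigma = 30))), "non-positive")
})

test_that("shaft estimate is insensitive to bouton density", {
  # same tube rendered with 2 vs 9 boutons: G-profile background level
  # should barely move (the bouton mass lives in the foreground block)
  dims <- c(128L, 128L, 40L); vs <- c(0.26, 0.26, 0.8)
  shaft <- sapply(c(2L, 8L), function(nb) {
    ax <- synthetic_axon(extent = dims * vs, n_boutons = nb, seed = 99,
                         min_spacing = 2.2)
    sc <- render_stack(ax, imaging_conditions(seed = 99), dim = dims,
                       voxel_size = vs)
    tr <- resample_trace(sc$traces[[1]], 4, vs)
    gp <- normalize_profile(intensity_profile(sc$stack, tr,
                                              filter_spec("gaussian")))
    lp <- normalize_profile(intensity_profile(
      sc$stack, tr, filter_spec("log_xy_multiscale")))
    shaft_intensity(fit_peaks(gp, init = fit_peaks(lp)))
  })
  # denser boutons pull the unit-mean normalization down, which lowers the
  # normalized shaft; the background itself must not collapse
  expect_gt(min(shaft), 0.5)
  expect_lt(abs(diff(shaft)) / mean(shaft), 0.45)
})

test_that("adding foreground peaks improves on a background-only fit", {
  s <- seq(0, 40, by = 0.1)
  y <- 1 + 1.2 * exp(-(s - 18)^2 / (2 * 0.8^2))
  prof <- manual_profile(s, y, normalized = TRUE)
  full <- fit_peaks(prof)
  # background-only residual: best wide-Gaussian fit cannot absorb the bump
  expect_gt(nrow(full$foreground), 0L)
  bg_only <- sum((y - predict(full, s, component = "background"))^2)
  expect_lt(full$residual_ss, bg_only)
})

test_that("the elimination/merge loop terminates within its peak budget", {
  s <- seq(0, 35, by = 0.25)
  set.seed(8)
  y <- pmax(1 + 0.15 * sin(s) + rnorm(length(s), sd = 0.05), 0.2)
  fit <- fit_peaks(manual_profile(s, y, normalized = TRUE))
  expect_lte(fit$passes, 2 * ceiling(35 / 0.5) + 10)
  expect_true(all(fit$foreground$a >= 0.3) || nrow(fit$foreground) == 0)
})

test_that("degenerate profiles are rejected or short-circuited", {
  expect_error(fit_peaks(manual_profile(c(0, 0.5), c(1, 1),
                                        normalized = TRUE)), "shorter")
  z <- fit_peaks(manual_profile(seq(0, 30, 0.25), rep(0, 121),
                                normalized = TRUE))
  expect_equal(nrow(z$foreground), 0L)
  expect_equal(z$residual_ss, 0)
})
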