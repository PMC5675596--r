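# Registration, greedy matching, fill-in and plasticity statistics.

test_that("registration maps interpolate, stretch, shift and invert", {
  id <- build_registration(c(10, 20), c(10, 20))
  expect_equal(apply_registration(id, c(10, 15, 20)), c(10, 15, 20))
  st <- build_registration(c(10, 20), c(12, 24))
  expect_equal(apply_registration(st, c(10, 15, 20)), c(12, 18, 24))
  # terminal-segment extrapolation keeps the edge slopes
  expect_equal(apply_registration(st, c(5, 25)), c(6, 30))
  sh <- build_registration(10, 13)
  expect_equal(apply_registration(sh, c(0, 10, 50)), c(3, 13, 53))
  # inverse composes to identity on fiducials
  inv <- invert_registration(st)
  expect_equal(apply_registration(inv, apply_registration(st, c(10, 17, 20))),
               c(10, 17, 20), tolerance = 1e-9)
  expect_error(build_registration(c(10, 5), c(1, 2)), "increasing")
})

test_that("greedy matching is one-to-one, bounded and symmetric", {
  a <- c(2, 6.1, 11, 18)
  m <- match_sites(a, a)
  expect_equal(nrow(m$matches), 4L)
  expect_equal(m$matches$dist, rep(0, 4))
  expect_length(m$unmatched_a, 0)
  # one empty side
  e <- match_sites(numeric(0), a)
  expect_equal(nrow(e$matches), 0L)
  expect_equal(e$unmatched_b, 1:4)
  # distance cap respected
  far <- match_sites(c(0), c(10), max_dist = 2)
  expect_equal(nrow(far$matches), 0L)
  # symmetry for well-separated sites
  b <- a + c(0.2, -0.3, 0.25, -0.1)
  ab <- match_sites(a, b)$matches
  ba <- match_sites(b, a)$matches
  expect_equal(ab[order(ab$i_a), c("i_a", "i_b")],
               ba[order(ba$i_b), c("i_b", "i_a")],
               ignore_attr = TRUE)
})

test_that("jittered sites are matched correctly almost always", {
  set.seed(31)
  correct <- 0; total <- 0
  for (rep in 1:100) {
    truth <- cumsum(runif(50, 2.5, 4))
    obs <- truth + rnorm(50, sd = 0.3)
    m <- match_sites(truth, obs, max_dist = 2)$matches
    correct <- correct + sum(m$i_a == m$i_b)
    total <- total + 50
  }
  expect_gte(correct / total, 0.98)
})

test_that("fill-in reads the registered profile value on the weight scale", {
  s <- seq(0, 30, by = 0.1)
  prof <- manual_profile(s, 0.8 + 0.4 * exp(-(s - 15)^2 / 2),
                         normalized = TRUE)
  # at shaft level the filled weight is ~1
  r <- fill_missing(5, prof, shaft = 0.8)
  expect_true(r$ok)
  expect_equal(r$weight, 1, tolerance = 0.01)
  # registered position is used
  map <- build_registration(c(0, 30), c(0 + 10, 30 + 10))
  r2 <- fill_missing(5, prof, map = map, shaft = 0.8)
  expect_equal(r2$position, 15)
  expect_equal(r2$weight, 1.2 / 0.8, tolerance = 0.01)
  # outside the span: flagged, not guessed
  r3 <- fill_missing(29, prof, map = map, shaft = 0.8)
  expect_false(r3$ok)
  expect_true(is.na(r3$weight))
  # raw profile value without the shaft division
  r4 <- fill_missing(15, prof, shaft = 0.8, divide_shaft = FALSE)
  expect_equal(r4$weight, 1.2, tolerance = 0.01)
})

test_that("static weights yield zero significant fractions and chance", {
  w <- matrix(rep(c(3, 5, 8, 2.5), 4), ncol = 4)
  fr <- plasticity_fractions(w)
  expect_true(all(fr$added == 0 & fr$eliminated == 0 &
                    fr$weight_changed == 0))
  ch <- chance_level(w, n_boot = 20, seed = 1)
  expect_true(all(ch$added == 0 & ch$eliminated == 0 &
                    ch$weight_changed == 0))
})

test_that("a programmed addition among stable sites is counted once", {
  w0 <- rep(5, 100); w1 <- w0
  w0[1] <- 0.5; w1[1] <- 10  # site 1: absent then large
  fr <- plasticity_fractions(cbind(w0, w1))
  expect_equal(fr$added, 0.01)
  expect_equal(fr$added_sd, sqrt(1) / 100)
  expect_equal(fr$eliminated, 0)
})

test_that("chance level is deterministic under a seed", {
  set.seed(77)
  w <- simulate_weight_pairs(exp(runif(60, log(1), log(10))), 0.24, 5,
                             seed = 77)
  a <- chance_level(w, n_boot = 30, seed = 123)
  b <- chance_level(w, n_boot = 30, seed = 123)
  expect_identical(a, b)
  c2 <- chance_level(w, n_boot = 30, seed = 124)
  expect_false(identical(a, c2))
})

test_that("noise-only series stay at chance; real additions stand out", {
  set.seed(55)
  w0 <- exp(runif(300, log(1), log(10)))
  w <- simulate_weight_pairs(w0, 0.24, 4, seed = 55)
  fr <- plasticity_fractions(w)
  ch <- chance_level(w, n_boot = 50, seed = 9)
  for (col in c("added", "eliminated", "weight_changed")) {
    excess <- fr[[col]] - ch[[col]]
    poisson_sd <- pmax(fr[[paste0(col, "_sd")]], 1 / nrow(w))
    expect_true(all(excess <= 3 * poisson_sd),
                label = sprintf("%s within 3 sd of chance", col))
  }
  # program additions at session 3: 30 sites appear
  w2 <- w
  w2[1:30, 1:2] <- matrix(runif(60, 0.2, 0.5), 30)
  w2[1:30, 3:4] <- matrix(runif(60, 6, 10), 30)
  fr2 <- plasticity_fractions(w2)
  ch2 <- chance_level(w2, n_boot = 50, seed = 9)
  expect_gt(fr2$added[2],
            ch2$added[2] + 3 * max(fr2$added_sd[2], 1 / nrow(w2)))
  expect_gt(fr2$added[3],
            ch2$added[3] + 3 * max(fr2$added_sd[3], 1 / nrow(w2)))
})
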