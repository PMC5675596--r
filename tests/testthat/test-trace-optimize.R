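# Trace fitness and optimization against rendered tubes.

test_that("fitness is zero on an empty stack and negative under bending", {
  st <- image_stack(array(0, c(30, 20, 10)), c(0.26, 0.26, 0.8))
  tr <- axon_trace(cbind(seq(1, 6, by = 0.52), 2.6, 4))
  expect_equal(trace_fitness(st, tr), 0)
  # displacing one interior node activates only the stiffness penalty
  nodes <- tr$nodes
  nodes[5, 2] <- nodes[5, 2] + 0.5
  expect_lt(trace_fitness(st, axon_trace(nodes)), 0)
})

test_that("the on-axis trace outscores a laterally offset copy", {
  st <- straight_tube_stack()
  tr <- tube_axis_trace(st)
  off <- tr$nodes; off[, 2] <- off[, 2] + 0.26
  expect_gt(trace_fitness(st, tr), trace_fitness(st, axon_trace(off)))
})

test_that("fitness is equivariant under integer-voxel translations", {
  st <- straight_tube_stack(dim = c(60L, 40L, 14L))
  tr <- tube_axis_trace(st, n = 21L)
  f0 <- trace_fitness(st, tr)
  # shift stack content and trace by one voxel in y
  v <- st$values
  v2 <- array(0, dim(v)); v2[, 2:dim(v)[2], ] <- v[, 1:(dim(v)[2] - 1), ]
  st2 <- image_stack(v2, st$voxel_size)
  tr2 <- axon_trace(sweep(tr$nodes, 2, c(0, st$voxel_size[2], 0), `+`))
  expect_equal(trace_fitness(st2, tr2), f0, tolerance = 1e-6)
})

test_that("an on-axis trace is a lateral fixed point of the optimizer", {
  st <- straight_tube_stack()
  tr <- tube_axis_trace(st)
  opt <- optimize_trace(st, tr)
  # nodes may slide along the axis (a neutral direction for a straight
  # tube) but must not move off it
  expect_lt(max(abs(opt$nodes[, 2:3] - tr$nodes[, 2:3])), 0.05)
  expect_gte(trace_fitness(st, opt), trace_fitness(st, tr))
})

test_that("optimization pulls a jittered trace back to the axis", {
  st <- straight_tube_stack()
  tr <- tube_axis_trace(st)
  set.seed(11)
  jit <- tr$nodes
  jit[, 2] <- jit[, 2] + runif(nrow(jit), -0.26, 0.26)
  jit[, 3] <- jit[, 3] + runif(nrow(jit), -0.4, 0.4)
  jt <- axon_trace(jit)
  opt <- optimize_trace(st, jt)
  resid_before <- sqrt(mean((jit[, 2] - 6.0)^2 + (jit[, 3] - 6.4)^2))
  resid_after <- sqrt(mean((opt$nodes[, 2] - 6.0)^2 +
                             (opt$nodes[, 3] - 6.4)^2))
  expect_lt(resid_after, resid_before / 5)
  expect_gte(trace_fitness(st, opt), trace_fitness(st, jt))
  expect_true(attr(opt, "termination") %in% c("converged", "max_iter"))
})

test_that("independent jittered traces converge toward a common layout", {
  st <- straight_tube_stack()
  tr <- tube_axis_trace(st, n = 31L)
  set.seed(21)
  jitter_one <- function() {
    nd <- tr$nodes
    nd[, 2] <- nd[, 2] + rnorm(nrow(nd), sd = 0.26)
    nd[, 3] <- nd[, 3] + rnorm(nrow(nd), sd = 0.26)
    axon_trace(nd)
  }
  traces <- replicate(5, jitter_one(), simplify = FALSE)
  opts <- lapply(traces, function(t) optimize_trace(st, t))
  pair_dist <- function(ts) {
    ps <- utils::combn(length(ts), 2)
    mean(apply(ps, 2, function(ij)
      mean(sqrt(rowSums((ts[[ij[1]]]$nodes - ts[[ij[2]]]$nodes)^2)))))
  }
  expect_lt(pair_dist(opts), pair_dist(traces) / 3)
})

test_that("dominant stiffness straightens a trace on a noisy image", {
  set.seed(5)
  st <- image_stack(array(runif(40 * 30 * 10, 0, 5), c(40, 30, 10)),
                    c(0.26, 0.26, 0.8))
  x <- seq(1.5, 8.5, length.out = 25)
  nodes <- cbind(x, 4 + 0.4 * sin(x), 4 + 0.3 * cos(2 * x))
  cfg <- pipeline_config(stiffness_alpha = 1e4, opt_max_iter = 500L)
  opt <- optimize_trace(st, axon_trace(nodes), cfg)
  # collinearity: residual of each node from the best-fit line
  ctr <- colMeans(opt$nodes)
  sv <- svd(sweep(opt$nodes, 2, ctr))
  resid <- sweep(opt$nodes, 2, ctr) -
    (sweep(opt$nodes, 2, ctr) %*% sv$v[, 1]) %*% t(sv$v[, 1])
  expect_lt(max(sqrt(rowSums(resid^2))), 1e-3)
})

test_that("resampling keeps endpoints, length and existing densities", {
  tr <- axon_trace(cbind(c(0, 10), 0, 0))
  rs <- resample_trace(tr, 4, c(0.26, 0.26, 0.8))
  expect_equal(nrow(rs$nodes), round(10 / 0.065) + 1)
  expect_equal(rs$nodes[1, ], tr$nodes[1, ])
  expect_equal(rs$nodes[nrow(rs$nodes), ], tr$nodes[2, ])
  expect_equal(trace_length(rs), 10, tolerance = 1e-9)

  # upsampling a smooth curved trace preserves its length closely
  x <- seq(0, 12, by = 0.52)
  crv <- axon_trace(cbind(x, 0.5 * sin(2 * pi * x / 10), 0))
  rs2 <- resample_trace(crv, 4, c(0.26, 0.26, 0.8))
  expect_equal(trace_length(rs2), trace_length(crv), tolerance = 1e-4)

  # resampling at the current density is a no-op
  rs3 <- resample_trace(rs, 4, c(0.26, 0.26, 0.8))
  expect_equal(rs3$nodes, rs$nodes, tolerance = 1e-9)
})
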