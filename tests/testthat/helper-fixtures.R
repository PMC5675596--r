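# Shared fixtures, built in code. Heavy renders are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small stack holding a straight tube along x at (y0, z0), Gaussian
# cross-section; intensities are analytic (no RNG)
straight_tube_stack <- function(dim = c(80L, 48L, 16L),
                                voxel_size = c(0.26, 0.26, 0.8),
                                y0 = 6.0, z0 = 6.4, sigma_xy = 0.35,
                                sigma_z = 0.65, peak = 200) {
  yc <- ((seq_len(dim[2]) - 0.5) * voxel_size[2] - y0)^2 / (2 * sigma_xy^2)
  zc <- ((seq_len(dim[3]) - 0.5) * voxel_size[3] - z0)^2 / (2 * sigma_z^2)
  plane <- peak * exp(-outer(yc, zc, `+`))
  vals <- aperm(array(plane, c(dim[2], dim[3], dim[1])), c(3, 1, 2))
  image_stack(vals, voxel_size, name = "tube")
}

# trace running along the tube axis
tube_axis_trace <- function(stack, y0 = 6.0, z0 = 6.4, margin = 2,
                            n = 41L) {
  ext <- dim(stack$values) * stack$voxel_size
  x <- seq(margin, ext[1] - margin, length.out = n)
  axon_trace(cbind(x, y0, z0), axon_id = "tube")
}

# deterministic rendered scene with known boutons (cached)
demo_scene <- function() {
  cache_fixture("demo_scene", {
    dims <- c(128L, 128L, 40L)
    vs <- c(0.26, 0.26, 0.8)
    ax <- synthetic_axon(extent = dims * vs, n_boutons = 5, seed = 42)
    sc <- render_stack(ax, imaging_conditions(seed = 7), dim = dims,
                       voxel_size = vs)
    list(axon = ax, scene = sc,
         trace = resample_trace(sc$traces[[1]], 4, vs))
  })
}

demo_detection <- function() {
  cache_fixture("demo_detection", {
    d <- demo_scene()
    detect_boutons(d$scene$stack, d$trace)
  })
}

# construct a peak_fit object directly from given peaks (for closed-form
# intensity/shaft checks without running the optimizer)
manual_peak_fit <- function(fg, bg, positions = seq(0, 50, by = 0.25)) {
  prof <- structure(
    list(positions = positions,
         values = rep(1, length(positions)),
         excluded = rep(FALSE, length(positions)),
         filter = filter_spec("log_xy_multiscale"), normalized = TRUE,
         axon_id = "manual", session_id = "s1"),
    class = "intensity_profile")
  structure(list(foreground = fg, background = bg, residual_ss = 0,
                 passes = 0L, converged = TRUE, profile = prof),
            class = "peak_fit")
}

# profile object built from explicit values (no imaging)
manual_profile <- function(s, v, excluded = rep(FALSE, length(s)),
                           normalized = FALSE) {
  structure(
    list(positions = s, values = v, excluded = excluded,
         filter = filter_spec("log_xy_multiscale"),
         normalized = normalized, axon_id = "manual", session_id = "s1"),
    class = "intensity_profile")
}
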