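# Ground-truth axon generation and stack rendering, so every pipeline
# stage can be exercised against known answers without microscope data.

#' Imaging conditions for synthetic rendering
#'
#' Multiplicative and noise factors a rendered stack is subject to:
#' `gain` models laser power / PMT voltage / window quality (shared by all
#' axons in a session), `rho` the per-axon volume density of fluorescent
#' molecules (expression level; scalar or one value per axon), `psf_sigma`
#' the anisotropic Gaussian point-spread function, and additive Gaussian
#' and/or Poisson noise.
#'
#' @param gain session gain factor, > 0 (sets the count scale).
#' @param rho expression factor(s), > 0.
#' @param psf_sigma `(sigma_xy, sigma_z)` in um.
#' @param noise_sd additive Gaussian noise s.d. in counts (0 disables).
#' @param poisson apply Poisson (shot) noise to the signal.
#' @param seed RNG seed recorded in the output metadata.
#' @return A list of class `imaging_conditions`.
#' @export
imaging_conditions <- function(gain = 1000, rho = 1,
                               psf_sigma = c(0.15, 0.6),
                               noise_sd = 10, poisson = FALSE, seed = 1L) {
  stopifnot(gain > 0, all(rho > 0), all(psf_sigma > 0), noise_sd >= 0)
  structure(list(gain = gain, rho = rho, psf_sigma = as.numeric(psf_sigma),
                 noise_sd = noise_sd, poisson = isTRUE(poisson),
                 seed = as.integer(seed)),
            class = "imaging_conditions")
}

#' Generate a ground-truth axon
#'
#' A gently curved 3D centerline inside the given physical extent, carrying
#' a tubular shaft plus Gaussian bouton blobs. The generator emulates
#' cytosolic labeling: total fluorescence is proportional to cytosol
#' volume, so the shaft contributes a line mass equal to its cross-section
#' area and each bouton contributes a blob of integrated mass equal to its
#' volume. Bouton volumes are drawn log-uniformly over the range observed
#' for cortical boutons in electron microscopy (about 0.05--1 um^3). Blob
#' widths follow from geometry: a solid sphere of volume `V` has per-axis
#' second moment `a^2/5` (radius `a`), so the Gaussian-equivalent width is
#' `sigma = a / sqrt(5)` times a small shape jitter; likewise the tube of
#' radius `r` renders with lateral width `r / 2`.
#'
#' @param extent physical volume size `(x, y, z)` in um.
#' @param length_um target centerline length.
#' @param n_boutons number of boutons.
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @param shaft_radius physical shaft radius, um.
#' @param bouton_volume_range bouton volume range in um^3, sampled
#'   log-uniformly.
#' @param sigma_jitter relative spread of bouton blob width around its
#'   volume-implied value (shape irregularity).
#' @param min_spacing minimum arc distance between boutons, um.
#' @param overhang_um rendered axon extends this far beyond each traced
#'   end, emulating that a traced segment is an excerpt of a longer axon
#'   (so intensity profiles do not roll off at the trace ends).
#' @param margin_um keep the centerline this far from the volume faces.
#' @param end_margin_um keep boutons this far from the trace ends.
#' @param curvature_amp lateral sinusoidal wobble amplitude, um.
#' @param struct_amp relative amplitude of the slow structural modulation
#'   of shaft brightness along the axon.
#' @param axon_id identifier.
#' @return Object of class `ground_truth_axon`: list with `centerline`
#'   (fine-sampled `m x 3` matrix, um), `arc_length`, `boutons`
#'   (data.frame `s_um`, `sigma_um`, `volume`), `shaft_radius`,
#'   `struct_amp`, `axon_id`.
#' @export
synthetic_axon <- function(extent = c(33.3, 33.3, 32), length_um = 26,
                           n_boutons = 5, seed = NULL, shaft_radius = 0.3,
                           bouton_volume_range = c(0.05, 1.0),
                           sigma_jitter = 0.15,
                           min_spacing = 3, overhang_um = 5,
                           margin_um = 4,
                           end_margin_um = 3, curvature_amp = 1.0,
                           struct_amp = 0.1, axon_id = "axon") {
  if (!is.null(seed)) set.seed(seed)
  L_full <- length_um + 2 * overhang_um
  stopifnot(L_full + 2 * margin_um <= sqrt(sum(extent[1:2]^2)))
  # straight diagonal backbone in xy with sinusoidal wobble, slow z drift
  z0 <- stats::runif(1, margin_um, extent[3] - margin_um)
  t <- seq(0, L_full, by = 0.05)
  theta <- stats::runif(1, 0, 2 * pi)
  dir2 <- c(cos(theta), sin(theta))
  # choose a start so the whole segment fits with margins
  p0 <- numeric(2)
  for (ax in 1:2) {
    lo <- margin_um + max(0, -dir2[ax] * L_full) + curvature_amp
    hi <- extent[ax] - margin_um - max(0, dir2[ax] * L_full) - curvature_amp
    if (lo > hi) { # direction does not fit; fall back to the diagonal
      dir2 <- c(1, 1) / sqrt(2)
      p0 <- rep(margin_um + curvature_amp, 2)
      break
    }
    p0[ax] <- stats::runif(1, lo, hi)
  }
  phase <- stats::runif(1, 0, 2 * pi)
  perp <- c(-dir2[2], dir2[1])
  wobble <- curvature_amp * sin(2 * pi * t / L_full + phase)
  zwob <- 0.5 * sin(2 * pi * t / L_full + stats::runif(1, 0, 2 * pi))
  centerline <- cbind(p0[1] + dir2[1] * t + perp[1] * wobble,
                      p0[2] + dir2[2] * t + perp[2] * wobble,
                      z0 + zwob)
  seg <- sqrt(rowSums(diff(centerline)^2))
  arc <- c(0, cumsum(seg))
  # traced span: the middle `length_um` of the rendered axon
  i0 <- which.min(abs(t - overhang_um))
  i1 <- which.min(abs(t - (overhang_um + length_um)))
  trace_span <- c(arc[i0], arc[i1])
  L <- trace_span[2] - trace_span[1]

  # bouton positions (trace coordinates): spaced draws by rejection
  pos <- numeric(0)
  guard <- 0L
  while (length(pos) < n_boutons && guard < 5000L) {
    cand <- stats::runif(1, end_margin_um, L - end_margin_um)
    if (!length(pos) || min(abs(pos - cand)) >= min_spacing)
      pos <- c(pos, cand)
    guard <- guard + 1L
  }
  if (length(pos) < n_boutons)
    stop("could not place ", n_boutons, " boutons at spacing ", min_spacing)
  pos <- sort(pos)
  volume <- exp(stats::runif(n_boutons, log(bouton_volume_range[1]),
                             log(bouton_volume_range[2])))
  # solid sphere of volume V: radius a, per-axis sd a/sqrt(5)
  a_sphere <- (3 * volume / (4 * pi))^(1 / 3)
  sigma <- a_sphere / sqrt(5) *
    stats::runif(n_boutons, 1 - sigma_jitter, 1 + sigma_jitter)
  boutons <- data.frame(s_um = pos, sigma_um = sigma, volume = volume)
  structure(list(centerline = centerline, arc_length = arc,
                 trace_span = trace_span, boutons = boutons,
                 shaft_radius = shaft_radius, struct_amp = struct_amp,
                 axon_id = as.character(axon_id)),
            class = "ground_truth_axon")
}

#' @export
print.ground_truth_axon <- function(x, ...) {
  cat(sprintf(
    "ground_truth_axon '%s': traced %.1f of %.1f um rendered, %d bouton(s)\n",
    x$axon_id, diff(x$trace_span), max(x$arc_length), nrow(x$boutons)))
  invisible(x)
}

# interpolate a point on the centerline at trace arc length s
centerline_at <- function(axon, s) {
  vapply(1:3, function(ax)
    stats::approx(axon$arc_length, axon$centerline[, ax],
                  xout = s + axon$trace_span[1])$y,
    numeric(1))
}

# deposit amplitude * exp(-sum(d^2 / (2 sigma^2))) into `vals` around `p`
deposit_gaussian <- function(vals, voxel_size, p, sigma, amplitude,
                             cutoff = 4) {
  d <- dim(vals)
  ix <- axis_window(p[1], cutoff * sigma[1], d[1], voxel_size[1])
  iy <- axis_window(p[2], cutoff * sigma[2], d[2], voxel_size[2])
  iz <- axis_window(p[3], cutoff * sigma[3], d[3], voxel_size[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(vals)
  ex <- exp(-(axis_centers(d[1], voxel_size[1])[ix] - p[1])^2 /
              (2 * sigma[1]^2))
  ey <- exp(-(axis_centers(d[2], voxel_size[2])[iy] - p[2])^2 /
              (2 * sigma[2]^2))
  ez <- exp(-(axis_centers(d[3], voxel_size[3])[iz] - p[3])^2 /
              (2 * sigma[3]^2))
  vals[ix, iy, iz] <- vals[ix, iy, iz] +
    amplitude * outer(outer(ex, ey), ez)
  vals
}

#' Render ground-truth axons into an image stack
#'
#' Builds the noiseless signal `gain * rho * (tube + bouton blobs)` --
#' both convolved with the anisotropic Gaussian PSF (applied analytically:
#' a Gaussian tube/blob convolved with a Gaussian PSF is again Gaussian,
#' with variances added) -- then applies Poisson and/or additive Gaussian
#' noise. Fluorescence is volume-proportional: the tube carries line mass
#' `pi * shaft_radius^2` per um and each bouton an integrated mass equal
#' to its volume, both times the expression factor `rho`.
#'
#' @param axons a `ground_truth_axon` or list of them.
#' @param cond an [imaging_conditions].
#' @param dim stack dimensions in voxels `(nx, ny, nz)`.
#' @param voxel_size voxel edge lengths, um.
#' @param name stack identifier.
#' @return List with `stack` (an [image_stack]), `traces` (ground-truth
#'   [axon_trace] per axon) and `boutons` (data.frame with `axon_id`,
#'   `s_um`, `sigma_um`, `height`, `volume`).
#' @export
render_stack <- function(axons, cond = imaging_conditions(),
                         dim = c(128L, 128L, 40L),
                         voxel_size = c(0.26, 0.26, 0.8),
                         name = "synthetic") {
  if (inherits(axons, "ground_truth_axon")) axons <- list(axons)
  stopifnot(all(vapply(axons, inherits, logical(1), "ground_truth_axon")))
  rho <- rep_len(cond$rho, length(axons))
  extent <- dim * voxel_size
  vals <- array(0, dim)
  step <- 0.05
  for (ai in seq_along(axons)) {
    ax <- axons[[ai]]
    if (any(ax$centerline < 0) ||
        any(sweep(ax$centerline, 2L, extent, `>`)))
      stop("axon '", ax$axon_id, "' lies outside the rendered volume")
    # solid tube of radius r: lateral second moment r^2/4
    sig_t <- sqrt((ax$shaft_radius / 2)^2 +
                    c(cond$psf_sigma[1], cond$psf_sigma[1],
                      cond$psf_sigma[2])^2)
    s_samp <- seq(0, max(ax$arc_length), by = step)
    pts <- vapply(1:3, function(k)
      stats::approx(ax$arc_length, ax$centerline[, k], xout = s_samp)$y,
      numeric(length(s_samp)))
    # line mass per sample: cross-section area x step, gently modulated
    mass_s <- rho[ai] * pi * ax$shaft_radius^2 * step *
      (1 + ax$struct_amp * sin(2 * pi * s_samp / max(ax$arc_length)))
    amp_s <- mass_s / ((2 * pi)^1.5 * prod(sig_t))
    contrib <- array(0, dim)
    for (i in seq_along(s_samp))
      contrib <- deposit_gaussian(contrib, voxel_size, pts[i, ], sig_t,
                                  amp_s[i])
    for (j in seq_len(nrow(ax$boutons))) {
      b <- ax$boutons[j, ]
      sig_b <- sqrt(b$sigma_um^2 +
                      c(cond$psf_sigma[1], cond$psf_sigma[1],
                        cond$psf_sigma[2])^2)
      amp_b <- rho[ai] * b$volume / ((2 * pi)^1.5 * prod(sig_b))
      contrib <- deposit_gaussian(contrib, voxel_size,
                                  centerline_at(ax, b$s_um), sig_b, amp_b)
    }
    vals <- vals + contrib
  }
  vals <- cond$gain * vals
  set.seed(cond$seed)
  if (cond$poisson) vals[] <- stats::rpois(length(vals), vals)
  if (cond$noise_sd > 0)
    vals <- vals + stats::rnorm(length(vals), sd = cond$noise_sd)
  vals <- pmax(vals, 0)
  traces <- lapply(axons, function(ax) {
    rows <- which(ax$arc_length >= ax$trace_span[1] - 1e-9 &
                    ax$arc_length <= ax$trace_span[2] + 1e-9)
    axon_trace(ax$centerline[rows[seq(1, length(rows), by = 4)], ],
               axon_id = ax$axon_id)
  })
  gt <- do.call(rbind, lapply(axons, function(ax) {
    if (nrow(ax$boutons) == 0L)
      return(data.frame(axon_id = character(0), s_um = numeric(0),
                        sigma_um = numeric(0), volume = numeric(0)))
    cbind(axon_id = ax$axon_id, ax$boutons)
  }))
  list(stack = image_stack(vals, voxel_size, name = name),
       traces = traces, boutons = gt)
}

#' Simulate repeated weight measurements under the noise model
#'
#' Each session's measured weight is the true weight plus Gaussian noise
#' of variance `alpha * w0 / 2`, independently across sessions, truncated
#' below at 0.01. Two such sessions reproduce `var(dw) = alpha <w>`.
#'
#' @param true_weights vector of true weights `w0 > 0`.
#' @param alpha noise slope.
#' @param n_sessions number of sessions (columns).
#' @param seed RNG seed (same seed, same table).
#' @return Numeric matrix, sites x sessions.
#' @export
simulate_weight_pairs <- function(true_weights, alpha = 0.24,
                                  n_sessions = 2, seed = NULL) {
  stopifnot(all(true_weights > 0), alpha > 0, n_sessions >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_weights)
  w <- matrix(stats::rnorm(n * n_sessions,
                           mean = rep(true_weights, n_sessions),
                           sd = rep(sqrt(alpha * true_weights / 2),
                                    n_sessions)),
              nrow = n)
  pmax(w, 0.01)
}

#' CLEM reference measurements
#'
#' Bundled table of 19 putative boutons on four axon segments measured
#' with correlative light and electron microscopy: the 2PLSM bouton
#' weight, the LM-bouton probability at `alpha = 0.24`,
#' `w_threshold = 2.0`, and the EM bouton volume, mitochondria volume and
#' PSD surface area where the structure was found in EM. Bouton 8 is a
#' terminal bouton (no weight: it does not sit on the axon centerline) and
#' bouton 7 abuts a branch point, which biases its weight; both are
#' excluded from weight-volume correlation analyses.
#'
#' @return data.frame with columns `axon`, `bouton_id`, `weight`,
#'   `p_bouton`, `volume_um3`, `mito_volume_um3`, `psd_area_um2`.
#' @export
clem_boutons <- function() {
  path <- system.file("extdata", "clem_boutons.csv", package = "boutonkit",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
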