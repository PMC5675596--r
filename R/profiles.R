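#' Profile filter specification
#'
#' @param kind one of `"log_xy_multiscale"` (bouton detection),
#'   `"gaussian"` (shaft estimation), or the fixed-size baselines
#'   `"mean_fixed"`, `"gaussian_fixed"`, `"median_fixed"` kept for
#'   comparison studies.
#' @param R_xy_range lateral size range in voxels (`log_xy_multiscale`).
#' @param n_scales number of evenly spaced scales spanning the range.
#' @param R_z axial size in (axial) voxels (`log_xy_multiscale`).
#' @param R_G size in voxels (`gaussian` / `gaussian_fixed`).
#' @param window odd voxel extent of the fixed baseline filters.
#' @param cutoff kernel truncation radius, multiples of the size.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("log_xy_multiscale", "gaussian",
                                 "mean_fixed", "gaussian_fixed",
                                 "median_fixed"),
                        R_xy_range = c(1.5, 3.0), n_scales = 4L, R_z = 2,
                        R_G = 2, window = 3L, cutoff = 4) {
  kind <- match.arg(kind)
  stopifnot(R_z > 0, R_G > 0, cutoff > 0, n_scales >= 1L)
  R_xy_range <- as.numeric(R_xy_range)
  if (length(R_xy_range) != 2L || R_xy_range[1] <= 0 ||
      diff(R_xy_range) < 0)
    stop("`R_xy_range` must be a nonempty positive range")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("`window` must be odd >= 1")
  structure(list(kind = kind, R_xy_range = R_xy_range,
                 n_scales = as.integer(n_scales), R_z = R_z, R_G = R_G,
                 window = window, cutoff = cutoff),
            class = "filter_spec")
}

# voxel-center coordinates along one axis
axis_centers <- function(n, v) (seq_len(n) - 0.5) * v

# index window around position p (um) with half-width h (um) on an axis
axis_window <- function(p, h, n, v) {
  lo <- max(1L, floor((p - h) / v - 0.5) + 1L)
  hi <- min(n, ceiling((p + h) / v + 0.5))
  if (lo > hi) integer(0) else lo:hi
}

#' Intensity profile along a trace
#'
#' Convolves the chosen filter with the image at every trace node: the
#' value at node `i` is `sum_voxels I(l) k(l - r_i) dV` over voxels within
#' the truncation radius (`dV` is the voxel volume). The multi-scale LoG
#' returns, at each node, the maximum response over its discrete scale set.
#' Fixed-size baseline filters (`mean_fixed`, `median_fixed`) instead pool
#' raw voxel values in a cubic window. Near stack borders the Gaussian
#' kernel is renormalized by its in-bounds mass; the LoG is truncated as
#' is. Filter sizes in voxels are converted to um with the lateral voxel
#' size (axial size `R_z` with the axial voxel size), so the anisotropy of
#' two-photon stacks is honored.
#'
#' @param stack an [image_stack].
#' @param trace an [axon_trace] (already optimized and resampled for the
#'   standard pipeline).
#' @param filter a [filter_spec].
#' @return Object of class `intensity_profile`: list with `positions`
#'   (arc length, um), `values`, `excluded` (logical, from the trace's
#'   exclusion intervals), `filter`, `normalized = FALSE`, `axon_id`,
#'   `session_id`.
#' @export
intensity_profile <- function(stack, trace, filter = filter_spec()) {
  stopifnot(inherits(stack, "image_stack"), inherits(trace, "axon_trace"),
            inherits(filter, "filter_spec"))
  v <- stack$voxel_size
  d <- dim(stack$values)
  vol <- prod(v)
  n <- nrow(trace$nodes)
  vals <- numeric(n)

  node_response <- function(p, h_xy, h_z, kernel_fun) {
    ix <- axis_window(p[1], h_xy, d[1], v[1])
    iy <- axis_window(p[2], h_xy, d[2], v[2])
    iz <- axis_window(p[3], h_z, d[3], v[3])
    if (!length(ix) || !length(iy) || !length(iz))
      return(c(0, 0))
    dx <- axis_centers(d[1], v[1])[ix] - p[1]
    dy <- axis_centers(d[2], v[2])[iy] - p[2]
    dz <- axis_centers(d[3], v[3])[iz] - p[3]
    I <- stack$values[ix, iy, iz, drop = FALSE]
    DX <- array(dx, c(length(ix), length(iy), length(iz)))
    DY <- array(rep(dy, each = length(ix)),
                c(length(ix), length(iy), length(iz)))
    DZ <- array(rep(dz, each = length(ix) * length(iy)),
                c(length(ix), length(iy), length(iz)))
    K <- kernel_fun(DX, DY, DZ)
    c(sum(I * K) * vol, sum(K) * vol)
  }

  if (filter$kind %in% c("log_xy_multiscale", "gaussian", "gaussian_fixed")) {
    if (filter$kind == "log_xy_multiscale") {
      scales_um <- seq(filter$R_xy_range[1], filter$R_xy_range[2],
                       length.out = filter$n_scales) * mean(v[1:2])
      Rz_um <- filter$R_z * v[3]
      # each scale is truncated at its own cutoff radius
      for (i in seq_len(n)) {
        best <- -Inf
        for (R_um in scales_um) {
          r <- node_response(trace$nodes[i, ], filter$cutoff * R_um,
                             filter$cutoff * Rz_um, function(dx, dy, dz)
                               log_xy_kernel(dx, dy, dz, R_um, Rz_um))
          best <- max(best, r[1])
        }
        vals[i] <- best
      }
    } else {
      R_um <- filter$R_G * mean(v[1:2])
      h <- filter$cutoff * R_um
      for (i in seq_len(n)) {
        r <- node_response(trace$nodes[i, ], h, h, function(dx, dy, dz)
          gaussian_kernel(dx, dy, dz, R_um))
        vals[i] <- if (r[2] > 0) r[1] / r[2] else 0
      }
    }
  } else {
    # fixed cubic-window baselines on raw voxel values
    half <- (filter$window - 1L) %/% 2L
    for (i in seq_len(n)) {
      idx <- pmin(pmax(round(trace$nodes[i, ] / v + 0.5), 1L), d)
      ix <- max(1L, idx[1] - half):min(d[1], idx[1] + half)
      iy <- max(1L, idx[2] - half):min(d[2], idx[2] + half)
      iz <- max(1L, idx[3] - half):min(d[3], idx[3] + half)
      w <- stack$values[ix, iy, iz]
      vals[i] <- if (filter$kind == "mean_fixed") mean(w) else
        stats::median(w)
    }
  }

  structure(
    list(positions = trace$arc_length, values = vals,
         excluded = in_exclusion(trace$arc_length, trace$exclusions),
         filter = filter, normalized = FALSE,
         axon_id = trace$axon_id, session_id = trace$session_id),
    class = "intensity_profile")
}

#' Normalize a profile to unit mean
#'
#' Divides the profile by its mean over non-excluded nodes, removing the
#' multiplicative factors tied to imaging conditions (laser power, PMT
#' voltage, window quality) and per-axon expression level, and isolating
#' the structural component. Fixed-size baseline filters are normalized by
#' their median instead (`method = "median"` is the default for those
#' kinds, matching how such baselines are conventionally scaled).
#'
#' @param profile an [intensity_profile] (raw).
#' @param method `"mean"` or `"median"`; default depends on the filter
#'   kind as described above.
#' @return The normalized [intensity_profile].
#' @export
normalize_profile <- function(profile, method = NULL) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (isTRUE(profile$normalized)) return(profile)
  if (is.null(method))
    method <- if (profile$filter$kind %in%
                  c("mean_fixed", "gaussian_fixed", "median_fixed"))
      "median" else "mean"
  method <- match.arg(method, c("mean", "median"))
  keep <- !profile$excluded
  if (!any(keep)) stop("profile not normalizable: all nodes excluded")
  m <- if (method == "mean") mean(profile$values[keep]) else
    stats::median(profile$values[keep])
  if (!is.finite(m) || m <= 0)
    stop("profile not normalizable: non-positive ", method)
  profile$values <- profile$values / m
  profile$normalized <- TRUE
  profile
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf(
    "intensity_profile '%s'/'%s': %d nodes over %.2f um, filter %s%s\n",
    x$axon_id, x$session_id, length(x$values),
    max(x$positions) - min(x$positions), x$filter$kind,
    if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' @export
plot.intensity_profile <- function(x, ...) {
  plot(x$positions, x$values, type = "l", xlab = "arc length (um)",
       ylab = if (x$normalized) "normalized intensity" else "intensity",
       main = sprintf("%s (%s)", x$axon_id, x$filter$kind), ...)
  if (any(x$excluded))
    graphics::points(x$positions[x$excluded], x$values[x$excluded],
                     col = "red", pch = 16, cex = 0.4)
  invisible(x)
}

#' Write a profile to CSV (columns s_um, value, excluded)
#' @param profile an [intensity_profile].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(
    data.frame(s_um = profile$positions, value = profile$values,
               excluded = profile$excluded),
    path, row.names = FALSE)
  invisible(path)
}
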