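#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline with its published
#' default. Filter sizes are in voxels (converted internally to um with the
#' stack's voxel sizes); arc-length quantities are in um.
#'
#' @param voxel_size voxel edge lengths `(vx, vy, vz)` um.
#' @param swc_units `"um"` or `"voxel"` SWC coordinate convention.
#' @param R_xy_range multi-scale LoG lateral size range, voxels.
#' @param n_scales number of LoG scales spanning `R_xy_range`.
#' @param R_z LoG axial size, voxels (axial voxel units).
#' @param R_G Gaussian (shaft) filter size, voxels.
#' @param cutoff kernel truncation radius in multiples of the size.
#' @param R_opt trace-optimization filter size, voxels.
#' @param lambda_opt node density during optimization, nodes/voxel.
#' @param lambda_profile node density for profile generation, nodes/voxel.
#' @param stiffness_alpha trace stiffness (Lagrange multiplier), >= 0.
#' @param opt_tol relative fitness-change stopping threshold.
#' @param opt_max_iter trace-optimization iteration cap.
#' @param fit_tol relative objective-change stopping threshold (peak fit).
#' @param fit_max_iter per-pass iteration cap (peak fit).
#' @param amp_threshold foreground amplitude below which a peak is
#'   eliminated (profile units; unit-mean profiles make 1 the baseline).
#' @param merge_dist foreground peaks closer than this are merged, um.
#' @param overlap_frac fraction of either peak's area above which two
#'   overlapping foreground peaks are merged.
#' @param fg_sigma_bounds foreground width bounds, um.
#' @param bg_sigma_min background width lower bound, um.
#' @param near_end_um flag boutons within this distance of a trace end.
#' @param alpha measurement-noise variance slope, `var(dw) = alpha <w>`.
#' @param w_threshold true-weight threshold defining an LM bouton.
#' @param match_max_dist greedy matcher distance cap, um.
#' @param p_sig significance level for plasticity event calls.
#' @param seed default RNG seed for stochastic steps.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(voxel_size = c(0.26, 0.26, 0.8),
                            swc_units = "um",
                            R_xy_range = c(1.5, 3.0),
                            n_scales = 4L,
                            R_z = 2,
                            R_G = 2,
                            cutoff = 4,
                            R_opt = 3,
                            lambda_opt = 0.5,
                            lambda_profile = 4,
                            stiffness_alpha = 0.001,
                            opt_tol = 1e-6,
                            opt_max_iter = 100L,
                            fit_tol = 1e-6,
                            fit_max_iter = 2000L,
                            amp_threshold = 0.3,
                            merge_dist = 1.0,
                            overlap_frac = 0.5,
                            fg_sigma_bounds = c(0.5, 2.0),
                            bg_sigma_min = 20,
                            near_end_um = 2,
                            alpha = 0.24,
                            w_threshold = 2.0,
                            match_max_dist = 2,
                            p_sig = 0.95,
                            seed = 1L) {
  cfg <- list(voxel_size = as.numeric(voxel_size), swc_units = swc_units,
              R_xy_range = as.numeric(R_xy_range),
              n_scales = as.integer(n_scales),
              R_z = R_z, R_G = R_G, cutoff = cutoff, R_opt = R_opt,
              lambda_opt = lambda_opt, lambda_profile = lambda_profile,
              stiffness_alpha = stiffness_alpha, opt_tol = opt_tol,
              opt_max_iter = as.integer(opt_max_iter), fit_tol = fit_tol,
              fit_max_iter = as.integer(fit_max_iter),
              amp_threshold = amp_threshold, merge_dist = merge_dist,
              overlap_frac = overlap_frac,
              fg_sigma_bounds = as.numeric(fg_sigma_bounds),
              bg_sigma_min = bg_sigma_min, near_end_um = near_end_um,
              alpha = alpha, w_threshold = w_threshold,
              match_max_dist = match_max_dist, p_sig = p_sig,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("R_z", "R_G", "cutoff", "R_opt", "lambda_opt", "lambda_profile",
           "opt_tol", "fit_tol", "amp_threshold", "merge_dist",
           "overlap_frac", "bg_sigma_min", "alpha", "w_threshold",
           "match_max_dist", "p_sig")
  for (nm in pos)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("config field `", nm, "` must be positive")
  if (cfg$stiffness_alpha < 0) stop("`stiffness_alpha` must be >= 0")
  if (length(cfg$R_xy_range) != 2L || cfg$R_xy_range[1] <= 0 ||
      diff(cfg$R_xy_range) < 0)
    stop("`R_xy_range` must be a nonempty positive range")
  if (any(cfg$fg_sigma_bounds <= 0) || diff(cfg$fg_sigma_bounds) < 0)
    stop("`fg_sigma_bounds` must be a positive range")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of [pipeline_config];
#' unknown fields are an error.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  user <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(user), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, user)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x))
    cat(sprintf("  %-16s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}
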