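# End-to-end putative-bouton detection on a single stack + trace.

#' Detect putative boutons and measure their weights
#'
#' Runs the profile stage of the pipeline on an (optimized) trace:
#' generates the multi-scale LoG profile, normalizes it to unit mean and
#' fits peaks to detect putative boutons; generates the Gaussian profile,
#' fits it seeded with the LoG peaks, and takes its fitted background as
#' the shaft intensity; then reports for every foreground peak the bouton
#' intensity (amplitude plus local LoG background), the shaft intensity
#' and the bouton weight `w = I_bouton / I_shaft`. The unit-mean
#' normalization cancels imaging gain and expression level, so weights are
#' comparable across axons and sessions. Records within `near_end_um` of a
#' trace end or inside an exclusion interval are flagged, not suppressed.
#'
#' @param stack an [image_stack].
#' @param trace an [axon_trace]; for the standard pipeline run
#'   [optimize_trace] and [resample_trace] first (see [detect_boutons_raw]
#'   for the one-call variant).
#' @param config a [pipeline_config].
#' @return A data.frame of bouton records with columns `site_id`,
#'   `axon_id`, `session_id`, `position_um`, `intensity`, `shaft`,
#'   `weight`, `p_bouton`, `near_end`, `in_exclusion`; the fitted models
#'   and profiles are attached as attributes `log_fit` and `g_fit`.
#' @export
detect_boutons <- function(stack, trace, config = pipeline_config()) {
  log_prof <- normalize_profile(intensity_profile(
    stack, trace, filter_spec("log_xy_multiscale",
                              R_xy_range = config$R_xy_range,
                              n_scales = config$n_scales,
                              R_z = config$R_z, cutoff = config$cutoff)))
  log_fit <- fit_peaks(log_prof, config)
  g_prof <- normalize_profile(intensity_profile(
    stack, trace, filter_spec("gaussian", R_G = config$R_G,
                              cutoff = config$cutoff)))
  g_fit <- fit_peaks(g_prof, config, init = log_fit)
  shaft <- shaft_intensity(g_fit)

  fg <- log_fit$foreground
  n <- nrow(fg)
  L <- trace_length(trace)
  model <- noise_model(alpha = config$alpha, w_threshold = config$w_threshold)
  if (n) {
    intensity <- vapply(seq_len(n), function(j)
      bouton_intensity(log_fit, j), numeric(1))
    weight <- intensity / shaft
    rec <- data.frame(
      site_id = seq_len(n),
      axon_id = trace$axon_id,
      session_id = trace$session_id,
      position_um = fg$mu,
      intensity = intensity,
      shaft = shaft,
      weight = weight,
      p_bouton = p_bouton(weight, model),
      near_end = fg$mu < config$near_end_um | fg$mu > L - config$near_end_um,
      in_exclusion = in_exclusion(fg$mu, trace$exclusions))
  } else {
    rec <- data.frame(site_id = integer(0), axon_id = character(0),
                      session_id = character(0), position_um = numeric(0),
                      intensity = numeric(0), shaft = numeric(0),
                      weight = numeric(0), p_bouton = numeric(0),
                      near_end = logical(0), in_exclusion = logical(0))
  }
  attr(rec, "log_fit") <- log_fit
  attr(rec, "g_fit") <- g_fit
  rec
}

#' Detect boutons from a raw manual trace
#'
#' Convenience wrapper running the full single-session pipeline: trace
#' optimization at the working node density, resampling to the profile
#' density, then [detect_boutons].
#'
#' @inheritParams detect_boutons
#' @return See [detect_boutons].
#' @export
detect_boutons_raw <- function(stack, trace, config = pipeline_config()) {
  tr <- resample_trace(trace, config$lambda_opt, stack$voxel_size)
  tr <- optimize_trace(stack, tr, config)
  tr <- resample_trace(tr, config$lambda_profile, stack$voxel_size)
  detect_boutons(stack, tr, config)
}

bouton_table_columns <- c("site_id", "axon_id", "session_id", "position_um",
                          "intensity", "shaft", "weight", "p_bouton",
                          "near_end", "in_exclusion")

#' Write bouton records to CSV
#'
#' Fixed header (`site_id, axon_id, session_id, position_um, intensity,
#' shaft, weight, p_bouton, near_end, in_exclusion`); numeric columns keep
#' full double precision so the table re-reads exactly. An empty record
#' list yields a header-only file.
#'
#' @param records data.frame from [detect_boutons].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bouton_table <- function(records, path) {
  missing_cols <- setdiff(bouton_table_columns, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(records[bouton_table_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a bouton table written by [write_bouton_table]
#' @param path CSV file path.
#' @return data.frame of bouton records.
#' @export
read_bouton_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(site_id = "integer",
                                        axon_id = "character",
                                        session_id = "character"))
  missing_cols <- setdiff(bouton_table_columns, names(out))
  if (length(missing_cols))
    stop("not a bouton table, missing: ", paste(missing_cols, collapse = ", "))
  out
}
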