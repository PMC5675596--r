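# Cross-session registration, bouton matching, fill-in of missing weights,
# and plasticity statistics.

#' Piecewise-linear registration from fiducial boutons
#'
#' Large stable boutons marked by the user in both sessions act as
#' fiducials; arc-length positions between fiducials are mapped
#' piecewise-linearly, and the terminal segment slopes are extended beyond
#' the fiducial span. A single fiducial degenerates to a pure shift.
#'
#' @param s_source,s_target fiducial arc-length positions (um) in the
#'   source and target session; both strictly increasing, equal length.
#' @return Object of class `registration_map`; call it like a function, or
#'   use [apply_registration].
#' @export
build_registration <- function(s_source, s_target) {
  stopifnot(length(s_source) == length(s_target), length(s_source) >= 1)
  if (length(s_source) > 1 &&
      (any(diff(s_source) <= 0) || any(diff(s_target) <= 0)))
    stop("fiducial positions must be strictly increasing in both sessions")
  obj <- structure(list(s_source = as.numeric(s_source),
                        s_target = as.numeric(s_target)),
                   class = "registration_map")
  obj
}

#' Apply a registration map to arc-length positions
#' @param map a [build_registration] result.
#' @param s positions (um) in the source session.
#' @return Registered positions in the target session.
#' @export
apply_registration <- function(map, s) {
  stopifnot(inherits(map, "registration_map"))
  src <- map$s_source; tgt <- map$s_target
  if (length(src) == 1L) return(s + (tgt - src))
  out <- stats::approx(src, tgt, xout = s, rule = 1)$y
  # extend terminal segment slopes beyond the fiducial span
  k <- length(src)
  slope_lo <- (tgt[2] - tgt[1]) / (src[2] - src[1])
  slope_hi <- (tgt[k] - tgt[k - 1]) / (src[k] - src[k - 1])
  lo <- s < src[1]; hi <- s > src[k]
  out[lo] <- tgt[1] + slope_lo * (s[lo] - src[1])
  out[hi] <- tgt[k] + slope_hi * (s[hi] - src[k])
  out
}

#' Invert a registration map
#' @param map a [build_registration] result.
#' @return The inverse `registration_map`.
#' @export
invert_registration <- function(map) {
  build_registration(map$s_target, map$s_source)
}

#' @export
print.registration_map <- function(x, ...) {
  cat(sprintf("registration_map: %d fiducial(s), span [%.2f, %.2f] -> [%.2f, %.2f] um\n",
              length(x$s_source), min(x$s_source), max(x$s_source),
              min(x$s_target), max(x$s_target)))
  invisible(x)
}

#' Greedy one-to-one matching of boutons across two sessions
#'
#' Registers session-A positions into session-B coordinates and repeatedly
#' matches the globally closest unmatched pair whose registered arc-length
#' distance is at most `max_dist`; the rest are reported unmatched.
#'
#' @param s_a,s_b putative-bouton arc-length positions (um) in sessions A
#'   and B.
#' @param map a `registration_map` from A to B, or `NULL` for identity.
#' @param max_dist maximum registered distance for a match, um.
#' @return List with `matches` (data.frame `i_a`, `i_b`, `dist`),
#'   `unmatched_a`, `unmatched_b` (index vectors).
#' @export
match_sites <- function(s_a, s_b, map = NULL, max_dist = 2) {
  sa <- if (is.null(map)) as.numeric(s_a) else apply_registration(map, s_a)
  sb <- as.numeric(s_b)
  na <- length(sa); nb <- length(sb)
  matches <- data.frame(i_a = integer(0), i_b = integer(0),
                        dist = numeric(0))
  if (na && nb) {
    D <- abs(outer(sa, sb, `-`))
    free_a <- rep(TRUE, na); free_b <- rep(TRUE, nb)
    repeat {
      Dv <- D
      Dv[!free_a, ] <- Inf
      Dv[, !free_b] <- Inf
      best <- which.min(Dv)
      if (!length(best) || Dv[best] > max_dist) break
      ia <- (best - 1L) %% na + 1L
      ib <- (best - 1L) %/% na + 1L
      matches <- rbind(matches,
                       data.frame(i_a = ia, i_b = ib, dist = Dv[best]))
      free_a[ia] <- FALSE; free_b[ib] <- FALSE
      if (!any(free_a) || !any(free_b)) break
    }
  }
  list(matches = matches,
       unmatched_a = setdiff(seq_len(na), matches$i_a),
       unmatched_b = setdiff(seq_len(nb), matches$i_b))
}

#' Fill in a missing bouton weight from the intensity profile
#'
#' A site detected in some sessions but missed in another still has a
#' well-defined weight there: the normalized profile value interpolated at
#' the registered position, divided (by default) by that session's shaft
#' intensity so the value stays on the weight scale.
#'
#' @param s_source site position (um) in the session where it was
#'   detected.
#' @param profile normalized [intensity_profile] of the missing session.
#' @param map `registration_map` from the source session to the missing
#'   session, or `NULL` for identity.
#' @param shaft shaft intensity of the missing session ([shaft_intensity]).
#' @param divide_shaft divide by `shaft`; set `FALSE` to take the raw
#'   normalized profile value.
#' @return List with `weight`, `position` (registered, um) and `ok`
#'   (`FALSE` when the registered position falls outside the profile span,
#'   in which case the site must be excluded from statistics).
#' @export
fill_missing <- function(s_source, profile, map = NULL, shaft = 1,
                         divide_shaft = TRUE) {
  stopifnot(inherits(profile, "intensity_profile"),
            isTRUE(profile$normalized), shaft > 0)
  pos <- if (is.null(map)) s_source else apply_registration(map, s_source)
  rng <- range(profile$positions)
  if (pos < rng[1] || pos > rng[2])
    return(list(weight = NA_real_, position = pos, ok = FALSE))
  val <- stats::approx(profile$positions, profile$values, xout = pos)$y
  list(weight = if (divide_shaft) val / shaft else val,
       position = pos, ok = TRUE)
}

#' Fractions of significant plasticity events over time
#'
#' For every session after the first, classifies each matched site by the
#' event probabilities between the reference (first) session and that
#' session, and reports the fraction of sites whose probability of
#' addition, elimination, or weight change (potentiation and depression
#' combined) exceeds `p_sig`. Standard deviations follow Poisson counting
#' statistics, `sqrt(count) / n_sites`.
#'
#' @param weights numeric matrix, sites x sessions (column 1 is the
#'   reference session); filled-in weights included.
#' @param model a [noise_model].
#' @param p_sig significance level on the event probability (default
#'   0.95).
#' @return data.frame with one row per later session: `session`,
#'   `added`, `eliminated`, `weight_changed` (fractions) and their `_sd`
#'   columns, plus `n_sites`.
#' @export
plasticity_fractions <- function(weights, model = noise_model(),
                                 p_sig = 0.95) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) >= 1, ncol(weights) >= 2, p_sig > 0.5)
  n <- nrow(weights)
  out <- lapply(2:ncol(weights), function(t) {
    ev <- event_probabilities(weights[, 1], weights[, t], model)
    n_add <- sum(ev$added > p_sig)
    n_eli <- sum(ev$eliminated > p_sig)
    n_wch <- sum(ev$potentiated > p_sig | ev$depressed > p_sig)
    data.frame(session = t,
               added = n_add / n, added_sd = sqrt(n_add) / n,
               eliminated = n_eli / n, eliminated_sd = sqrt(n_eli) / n,
               weight_changed = n_wch / n, weight_changed_sd = sqrt(n_wch) / n,
               n_sites = n)
  })
  do.call(rbind, out)
}

#' Chance level of significant-event fractions
#'
#' Bootstrap baseline for [plasticity_fractions]: in each replicate the
#' weights of every site are independently permuted across sessions,
#' destroying any temporal structure while preserving each site's weight
#' set, and the significant-event fractions are recomputed. The mean over
#' replicates is the level expected from measurement noise alone.
#'
#' @inheritParams plasticity_fractions
#' @param n_boot number of shuffle replicates.
#' @param seed RNG seed (same seed, same output).
#' @return data.frame like [plasticity_fractions] (fractions are replicate
#'   means; `_sd` columns are replicate standard deviations).
#' @export
chance_level <- function(weights, model = noise_model(), p_sig = 0.95,
                         n_boot = 100, seed = NULL) {
  weights <- as.matrix(weights)
  stopifnot(ncol(weights) >= 2)
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(n_boot), function(b) {
    shuf <- t(apply(weights, 1L, sample))
    plasticity_fractions(shuf, model, p_sig)
  })
  template <- reps[[1]]
  for (col in c("added", "eliminated", "weight_changed")) {
    mat <- sapply(reps, function(r) r[[col]])
    mat <- matrix(mat, nrow = nrow(template))
    template[[col]] <- rowMeans(mat)
    template[[paste0(col, "_sd")]] <- apply(mat, 1L, stats::sd)
  }
  template
}
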