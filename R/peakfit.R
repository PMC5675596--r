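# Peak decomposition of intensity profiles: a varying number of narrow
# foreground Gaussians (putative boutons) plus a fixed number of wide
# background Gaussians (slowly varying baseline), fitted by constrained
# least squares with backward elimination and merging of foreground peaks.

gauss_area <- function(a, sigma) a * sigma * sqrt(2 * pi)

# background component layout: centers anchored at the trace ends (so the
# non-negative sum can represent a flat baseline without sagging there)
# and widths wide enough that the sum is nearly constant between centers
bg_layout <- function(s0, s1, Nb, sigma_min = 20) {
  mu <- if (Nb == 1L) (s0 + s1) / 2 else seq(s0, s1, length.out = Nb)
  sigma <- max(sigma_min, (s1 - s0) / (2 * max(Nb - 1L, 1L)))
  list(mu = mu, sigma = rep(sigma, Nb))
}

# numerical overlap area of two Gaussian curves (integral of the min)
gauss_overlap <- function(a1, mu1, s1, a2, mu2, s2, step = 0.02) {
  lo <- min(mu1 - 5 * s1, mu2 - 5 * s2)
  hi <- max(mu1 + 5 * s1, mu2 + 5 * s2)
  x <- seq(lo, hi, by = step)
  f1 <- a1 * exp(-(x - mu1)^2 / (2 * s1^2))
  f2 <- a2 * exp(-(x - mu2)^2 / (2 * s2^2))
  sum(pmin(f1, f2)) * step
}

#' Fit foreground and background peaks to an intensity profile
#'
#' Decomposes a unit-mean profile into `Nf` narrow foreground Gaussians
#' (candidate boutons, width constrained to `fg_sigma_bounds`, default
#' 0.5--2 um) and `Nb = ceiling(L / 25um)` wide background Gaussians
#' (width >= `bg_sigma_min`, default 20 um, so the baseline varies slowly),
#' by minimizing the sum of squared residuals under bound constraints.
#' The fit starts from `Nf = ceiling(L / 0.5um)` uniformly spaced
#' foreground peaks (far more than the expected bouton count) and proceeds
#' backward-elimination style: after each constrained descent converges
#' (relative objective change below `fit_tol`), one foreground peak with
#' re-fitted amplitude below `amp_threshold` is eliminated -- or, if none,
#' one qualifying pair (centers closer than `merge_dist` or overlap area
#' above `overlap_frac` of either peak's area) is merged -- and the model
#' is re-optimized, until no candidate remains.
#'
#' @param profile a normalized [intensity_profile].
#' @param config a [pipeline_config].
#' @param init optional `peak_fit` whose peaks seed the fit (used when
#'   fitting the Gaussian shaft profile from the LoG fit); its centers must
#'   lie within the profile span.
#' @return An object of class `peak_fit`: list with data.frames
#'   `foreground` and `background` (columns `a`, `mu`, `sigma`),
#'   `residual_ss`, `passes`, `converged` and the `profile` it was fitted
#'   to. Supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals` and `plot`.
#' @export
fit_peaks <- function(profile, config = pipeline_config(), init = NULL) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (!isTRUE(profile$normalized))
    warning("fitting a non-normalized profile; weights assume unit mean")
  s <- profile$positions
  y <- profile$values
  use <- !profile$excluded
  s0 <- min(s); s1 <- max(s)
  L <- s1 - s0
  if (L < 1) stop("profile span shorter than 1 um; cannot fit peaks")
  Nb <- ceiling(L / 25)
  sgb <- config$fg_sigma_bounds
  bg_sigma_max <- 1e4

  if (all(y == 0)) {
    out <- structure(
      list(foreground = data.frame(a = numeric(0), mu = numeric(0),
                                   sigma = numeric(0)),
           background = data.frame(a = rep(0, Nb),
                                   mu = bg_layout(s0, s1, Nb)$mu,
                                   sigma = bg_layout(s0, s1, Nb,
                                                     config$bg_sigma_min)$sigma),
           residual_ss = 0, passes = 0L, converged = TRUE,
           profile = profile),
      class = "peak_fit")
    return(out)
  }

  if (is.null(init)) {
    Nf <- ceiling(L / 0.5)
    mu_f <- seq(s0, s1, length.out = Nf)
    lay <- bg_layout(s0, s1, Nb, config$bg_sigma_min)
    mu_b <- lay$mu
    a_b <- rep(1 / Nb, Nb)
    sg_b <- lay$sigma
    # seed the foreground from the profile minus a running-median
    # baseline: the median is insensitive to the bouton bumps, so seeds
    # appear only at genuine local excess and the baseline stays in the
    # background block (a dense overlapping foreground seeded from the
    # raw profile would absorb it)
    k <- min(length(y), 2L * ceiling(2.5 / max(stats::median(diff(s)),
                                               1e-6)) + 1L)
    base0 <- if (k >= 3) stats::runmed(y, k) else rep(stats::median(y),
                                                      length(y))
    resid0 <- y - base0
    sg_f <- rep(sgb[1], Nf)
    # correct seed amplitudes for the overlap of neighboring seeds
    spacing <- if (Nf > 1) mu_f[2] - mu_f[1] else L
    ovl <- sum(exp(-((-3:3) * spacing)^2 / (2 * sgb[1]^2)))
    a_f <- pmax(stats::approx(s, resid0, xout = mu_f, rule = 2)$y, 0) / ovl
    home_f <- mu_f
  } else {
    stopifnot(inherits(init, "peak_fit"))
    if (nrow(init$foreground) &&
        (min(init$foreground$mu) < s0 - 1e-9 ||
         max(init$foreground$mu) > s1 + 1e-9))
      stop("init peaks lie outside the profile span")
    a_f <- init$foreground$a; mu_f <- init$foreground$mu
    sg_f <- pmin(pmax(init$foreground$sigma, sgb[1]), sgb[2])
    a_b <- init$background$a; mu_b <- init$background$mu
    sg_b <- pmax(init$background$sigma, config$bg_sigma_min)
    Nb <- length(a_b)
    home_f <- mu_f
  }

  # Two structural guards keep the decomposition identifiable:
  # (1) background centers and widths are pinned at their smooth layout
  # and only background amplitudes are fitted (exactly, by non-negative
  # least squares) -- the width constraint exists to keep the baseline
  # slowly varying, which the pinned layout guarantees;
  # (2) each foreground peak's center stays within the merge distance of
  # the position that seeded it -- a candidate peak models local excess,
  # and letting candidates migrate lets a picket fence of narrow peaks
  # colonize baseline stretches the background basis cannot follow.
  run_fit <- function(a_f, mu_f, sg_f, a_b, mu_b, sg_b, home_f,
                      fit_bg = FALSE, maxit = config$fit_max_iter) {
    nf <- length(a_f)
    fit_gauss_cpp(
      s, y, use,
      c(a_f, a_b), c(mu_f, mu_b), c(sg_f, sg_b),
      la = rep(0, nf + Nb), ua = rep(Inf, nf + Nb),
      lmu = c(pmax(home_f - config$merge_dist, s0), mu_b),
      umu = c(pmin(home_f + config$merge_dist, s1), mu_b),
      lsg = c(rep(sgb[1], nf), sg_b), usg = c(rep(sgb[2], nf), sg_b),
      n_fg = nf, tol = config$fit_tol, maxit = maxit, fit_bg = fit_bg)
  }

  # fit the background once against the seeded foreground, then freeze it
  # while the dense candidate set is pruned; the joint fit is repeated
  # only on the pruned model (see the polish phase below)
  pre <- run_fit(a_f, mu_f, sg_f, a_b, mu_b, sg_b, home_f,
                 fit_bg = TRUE, maxit = 0L)
  a_b <- utils::tail(pre$a, Nb)

  passes <- 0L
  polish_cycles <- 0L
  polished <- FALSE
  converged <- TRUE
  repeat {
    fit <- run_fit(a_f, mu_f, sg_f, a_b, mu_b, sg_b, home_f,
                   fit_bg = polished)
    converged <- converged && fit$converged
    nf <- length(a_f)
    a_f <- utils::head(fit$a, nf); a_b <- utils::tail(fit$a, Nb)
    mu_f <- utils::head(fit$mu, nf); mu_b <- utils::tail(fit$mu, Nb)
    sg_f <- utils::head(fit$sigma, nf); sg_b <- utils::tail(fit$sigma, Nb)
    polished <- FALSE
    if (nf == 0L) {
      fit <- run_fit(a_f, mu_f, sg_f, a_b, mu_b, sg_b, home_f,
                     fit_bg = TRUE)
      a_b <- utils::tail(fit$a, Nb)
      break
    }
    passes <- passes + 1L

    # elimination first: drop the smallest sub-threshold amplitude
    small <- which(a_f < config$amp_threshold)
    if (length(small)) {
      drop <- small[which.min(a_f[small])]
      a_f <- a_f[-drop]; mu_f <- mu_f[-drop]; sg_f <- sg_f[-drop]
      home_f <- home_f[-drop]
      next
    }
    if (nf >= 2L) {
      # merge the closest qualifying pair
      ord <- order(mu_f)
      best <- NULL
      for (ii in seq_len(nf - 1L)) {
        j1 <- ord[ii]; j2 <- ord[ii + 1L]
        dist <- mu_f[j2] - mu_f[j1]
        qual <- dist < config$merge_dist
        if (!qual && dist < 5 * (sg_f[j1] + sg_f[j2])) {
          ov <- gauss_overlap(a_f[j1], mu_f[j1], sg_f[j1],
                              a_f[j2], mu_f[j2], sg_f[j2])
          qual <- ov > config$overlap_frac *
            min(gauss_area(a_f[j1], sg_f[j1]), gauss_area(a_f[j2], sg_f[j2]))
        }
        if (qual && (is.null(best) || dist < best$dist))
          best <- list(j1 = j1, j2 = j2, dist = dist)
      }
      if (!is.null(best)) {
        j1 <- best$j1; j2 <- best$j2
        wsum <- a_f[j1] + a_f[j2]
        mu_new <- if (wsum > 0)
          (a_f[j1] * mu_f[j1] + a_f[j2] * mu_f[j2]) / wsum else
            mean(c(mu_f[j1], mu_f[j2]))
        sg_new <- if (wsum > 0)
          (a_f[j1] * sg_f[j1] + a_f[j2] * sg_f[j2]) / wsum else
            mean(c(sg_f[j1], sg_f[j2]))
        a_new <- max(a_f[j1], a_f[j2])
        keep <- setdiff(seq_len(nf), c(j1, j2))
        a_f <- c(a_f[keep], a_new)
        mu_f <- c(mu_f[keep], mu_new)
        sg_f <- c(sg_f[keep], min(max(sg_new, sgb[1]), sgb[2]))
        home_f <- c(home_f[keep], mu_new)
        next
      }
    }
    # no elimination or merge candidate under the frozen background:
    # release the background and polish jointly; if that creates new
    # candidates, keep pruning (with the refreshed background frozen)
    if (!polished && polish_cycles < 10L) {
      polished <- TRUE
      polish_cycles <- polish_cycles + 1L
      next
    }
    break
  }

  ord <- order(mu_f)
  structure(
    list(foreground = data.frame(a = a_f[ord], mu = mu_f[ord],
                                 sigma = sg_f[ord]),
         background = data.frame(a = a_b, mu = mu_b, sigma = sg_b),
         residual_ss = fit$objective, passes = passes,
         converged = converged, profile = profile),
    class = "peak_fit")
}

peak_model_values <- function(object, s, component = c("all", "foreground",
                                                       "background")) {
  component <- match.arg(component)
  out <- numeric(length(s))
  if (component %in% c("all", "foreground") && nrow(object$foreground))
    out <- out + gauss_sum_cpp(s, object$foreground$a, object$foreground$mu,
                               object$foreground$sigma)
  if (component %in% c("all", "background") && nrow(object$background))
    out <- out + gauss_sum_cpp(s, object$background$a, object$background$mu,
                               object$background$sigma)
  out
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf(
    "peak_fit: %d foreground peak(s), %d background peak(s), SS = %.4g (%d pass(es))\n",
    nrow(x$foreground), nrow(x$background), x$residual_ss, x$passes))
  invisible(x)
}

#' @export
summary.peak_fit <- function(object, ...) {
  fg <- object$foreground
  if (nrow(fg))
    fg$intensity <- vapply(seq_len(nrow(fg)), function(j)
      bouton_intensity(object, j), numeric(1))
  out <- list(foreground = fg, background = object$background,
              residual_ss = object$residual_ss,
              n_nodes = length(object$profile$values))
  class(out) <- "summary.peak_fit"
  out
}

#' @export
print.summary.peak_fit <- function(x, ...) {
  cat(sprintf("Peak decomposition (%d nodes, residual SS %.4g)\n",
              x$n_nodes, x$residual_ss))
  cat("Foreground peaks:\n")
  print(x$foreground, digits = 4)
  cat("Background peaks:\n")
  print(x$background, digits = 4)
  invisible(x)
}

#' @export
coef.peak_fit <- function(object, ...) {
  rbind(cbind(object$foreground, kind = rep("foreground",
                                            nrow(object$foreground))),
        cbind(object$background, kind = rep("background",
                                            nrow(object$background))))
}

#' @export
predict.peak_fit <- function(object, newdata = NULL,
                             component = c("all", "foreground",
                                           "background"), ...) {
  s <- if (is.null(newdata)) object$profile$positions else as.numeric(newdata)
  peak_model_values(object, s, match.arg(component))
}

#' @export
fitted.peak_fit <- function(object, ...) {
  peak_model_values(object, object$profile$positions)
}

#' @export
residuals.peak_fit <- function(object, ...) {
  object$profile$values - fitted(object)
}

#' @export
plot.peak_fit <- function(x, ...) {
  s <- x$profile$positions
  plot(s, x$profile$values, type = "l", col = "grey30",
       xlab = "arc length (um)", ylab = "normalized intensity", ...)
  graphics::lines(s, peak_model_values(x, s, "background"), col = "red")
  graphics::lines(s, peak_model_values(x, s), col = "orange", lwd = 2)
  if (nrow(x$foreground))
    graphics::abline(v = x$foreground$mu, col = "cyan3", lty = 3)
  invisible(x)
}

#' Bouton intensity of a foreground peak
#'
#' The intensity of putative bouton `j` is the foreground amplitude plus
#' the fitted background evaluated at the peak center:
#' \eqn{I_j = a_j^f + \sum_k a_k^b \exp(-(\mu_j^f - \mu_k^b)^2 /
#' (2 (\sigma_k^b)^2))}.
#'
#' @param model a [fit_peaks] result (LoG profile fit).
#' @param j foreground peak index.
#' @return Intensity (profile units).
#' @export
bouton_intensity <- function(model, j) {
  stopifnot(inherits(model, "peak_fit"),
            j >= 1, j <= nrow(model$foreground))
  model$foreground$a[j] +
    peak_model_values(model, model$foreground$mu[j], "background")
}

#' Shaft intensity of an axon
#'
#' The fitted background of the Gaussian-filter profile, averaged over
#' non-excluded trace nodes. Because the background is constrained to vary
#' slowly (widths >= 20 um), this estimate is insensitive to how many
#' boutons sit on the axon.
#'
#' @param g_model a [fit_peaks] result fitted on the G (Gaussian) profile.
#' @param positions optional arc-length positions at which to average;
#'   defaults to the fitted profile's non-excluded nodes.
#' @return Shaft intensity (scalar, > 0).
#' @export
shaft_intensity <- function(g_model, positions = NULL) {
  stopifnot(inherits(g_model, "peak_fit"))
  if (is.null(positions)) {
    keep <- !g_model$profile$excluded
    positions <- g_model$profile$positions[keep]
  }
  val <- mean(peak_model_values(g_model, positions, "background"))
  if (!is.finite(val) || val <= 0)
    stop("non-positive shaft intensity; bouton weights undefined")
  val
}
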