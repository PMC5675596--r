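# Measurement-noise model for bouton weights and the probabilistic
# definition of LM boutons and plasticity events.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Measurement-noise model
#'
#' A measured bouton weight is modeled as `w = w0 + delta`, the true weight
#' plus Gaussian noise with variance proportional to the weight,
#' `var(delta) = alpha * w / 2`; the weight difference between two
#' independent sessions then satisfies `var(dw) = alpha * <w>`. An LM
#' bouton is a putative bouton whose *true* weight exceeds `w_threshold`.
#'
#' @param alpha variance slope (unitless); the default 0.24 comes from a
#'   repeated-imaging calibration in which the same axons were imaged
#'   seven times under varied laser power, PMT voltage and window quality.
#' @param w_threshold true-weight threshold defining an LM bouton; the
#'   default 2.0 is twice the normalized shaft intensity and matches the
#'   weight of the smallest varicosities confirmed by electron microscopy.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(alpha = 0.24, w_threshold = 2.0) {
  stopifnot(is.numeric(alpha), alpha > 0,
            is.numeric(w_threshold), w_threshold > 0)
  structure(list(alpha = alpha, w_threshold = w_threshold),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model: var(dw) = alpha <w>, alpha = %g, w_threshold = %g\n",
              x$alpha, x$w_threshold))
  invisible(x)
}

#' Probability that a putative bouton is an LM bouton
#'
#' Under the noise model, the probability that a putative bouton of
#' measured weight `w` has true weight above threshold is
#' \deqn{P(\mathrm{bouton}\mid w) = \tfrac12\left(1 +
#'   \mathrm{erf}\frac{w - w_{thr}}{\sqrt{\alpha w}}\right).}
#' `p_bouton(0)` is defined as 0 (the continuous limit).
#'
#' @param w measured weight(s), >= 0 (vectorized).
#' @param model a [noise_model].
#' @return Probabilities in `[0, 1]`.
#' @export
p_bouton <- function(w, model = noise_model()) {
  stopifnot(inherits(model, "noise_model"), all(w >= 0))
  out <- numeric(length(w))
  pos <- w > 0
  out[pos] <- 0.5 * (1 + erf((w[pos] - model$w_threshold) /
                               sqrt(model$alpha * w[pos])))
  out
}

#' Plasticity event probabilities between two sessions
#'
#' Given measured weights in an initial and a final session, computes the
#' probabilities of bouton addition, elimination, potentiation and
#' depression. With `P_i = p_bouton(wi)` and `P_f = p_bouton(wf)`:
#' added `= (1 - P_i) P_f`; eliminated `= P_i (1 - P_f)`;
#' potentiated `= P_i P_f (1 + erf((wf - wi)/sqrt(alpha (wi + wf))))/2`;
#' depressed is the mirror image. The four probabilities sum to
#' `1 - (1 - P_i)(1 - P_f)`; the missing mass is the event "absent in both
#' sessions".
#'
#' @param wi,wf measured weights in the initial and final session
#'   (vectorized, > 0; 0 allowed with `p_bouton(0) = 0`).
#' @param model a [noise_model].
#' @return data.frame with columns `added`, `eliminated`, `potentiated`,
#'   `depressed`.
#' @export
event_probabilities <- function(wi, wf, model = noise_model()) {
  stopifnot(length(wi) == length(wf))
  p_i <- p_bouton(wi, model)
  p_f <- p_bouton(wf, model)
  z <- (wf - wi) / sqrt(model$alpha * (wi + wf))
  data.frame(
    added = (1 - p_i) * p_f,
    eliminated = p_i * (1 - p_f),
    potentiated = p_i * p_f * 0.5 * (1 + erf(z)),
    depressed = p_i * p_f * 0.5 * (1 + erf(-z)))
}

#' Estimate the noise slope alpha from repeated measurements
#'
#' Pools weight pairs `(w1, w2)` of the same sites measured twice, bins
#' them by mean weight `<w> = (w1 + w2)/2` (equal-count quantile bins), and
#' fits `var(dw) = alpha <w>` by chi-square linear regression through the
#' origin: each bin contributes its sample variance of `dw = w1 - w2`,
#' weighted by the (normal-theory) variance of that sample variance,
#' `2 v^2 / (n - 1)`. The uncertainty of `alpha` is the standard deviation
#' over bootstrap resamples of the pairs (bin edges recomputed per
#' replicate).
#'
#' @param w1,w2 weights of the same sites in two sessions (> 0).
#' @param bins number of equal-count bins (default 8), or a numeric vector
#'   of bin edges on `<w>`.
#' @param n_boot bootstrap replicates for the uncertainty (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @param min_per_bin minimum pairs per bin.
#' @return Object of class `alpha_fit`: list with `alpha`, `alpha_sd`,
#'   `bins` (data.frame: bin mean weight, variance of dw, count),
#'   `n_pairs`.
#' @export
estimate_alpha <- function(w1, w2, bins = 8, n_boot = 200, seed = NULL,
                           min_per_bin = 10) {
  stopifnot(length(w1) == length(w2), all(w1 > 0), all(w2 > 0))
  mean_w <- (w1 + w2) / 2
  dw <- w1 - w2

  fit_once <- function(mean_w, dw) {
    if (length(bins) == 1L) {
      edges <- stats::quantile(mean_w, probs = seq(0, 1, length.out = bins + 1))
      edges[1] <- -Inf; edges[length(edges)] <- Inf
    } else edges <- bins
    grp <- cut(mean_w, edges, include.lowest = TRUE)
    tab <- table(grp)
    if (sum(tab > 0) < 2)
      stop("fewer than 2 nonempty bins; cannot regress")
    bad <- names(tab)[tab > 0 & tab < min_per_bin]
    if (length(bad))
      stop("degenerate bins with < ", min_per_bin, " pairs: ",
           paste(bad, collapse = ", "))
    m <- tapply(mean_w, grp, mean)
    v <- tapply(dw, grp, stats::var)
    n <- tapply(dw, grp, length)
    keep <- !is.na(v) & n >= 2
    m <- m[keep]; v <- v[keep]; n <- n[keep]
    # chi-square weights: var of a sample variance under normality
    wts <- (n - 1) / (2 * pmax(v, 1e-12)^2)
    list(alpha = sum(wts * m * v) / sum(wts * m^2),
         bins = data.frame(mean_w = as.numeric(m), var_dw = as.numeric(v),
                           n = as.integer(n)))
  }

  base <- fit_once(mean_w, dw)
  alpha_sd <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(dw), replace = TRUE)
      tryCatch(fit_once(mean_w[idx], dw[idx])$alpha,
               error = function(e) NA_real_)
    }, numeric(1))
    alpha_sd <- stats::sd(reps, na.rm = TRUE)
  }
  structure(list(alpha = base$alpha, alpha_sd = alpha_sd, bins = base$bins,
                 n_pairs = length(dw)),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("alpha_fit: alpha = %.4f", x$alpha))
  if (is.finite(x$alpha_sd)) cat(sprintf(" +/- %.4f (bootstrap s.d.)", x$alpha_sd))
  cat(sprintf("  [%d pairs, %d bins]\n", x$n_pairs, nrow(x$bins)))
  invisible(x)
}

#' @export
coef.alpha_fit <- function(object, ...) c(alpha = object$alpha)

#' Standardize weight differences under the noise model
#'
#' Rescales each pair's difference as `dw / sqrt(alpha <w>)`. If the noise
#' model holds at the given `alpha`, the standardized values follow a
#' standard normal distribution; a one-sample Kolmogorov-Smirnov test
#' against N(0, 1) is attached.
#'
#' @param w1,w2 weights of the same sites in two sessions.
#' @param alpha noise slope.
#' @return Numeric vector of standardized differences with attributes
#'   `ks_statistic` and `ks_p`.
#' @export
standardize_diffs <- function(w1, w2, alpha = 0.24) {
  stopifnot(alpha > 0, length(w1) == length(w2))
  z <- (w1 - w2) / sqrt(alpha * (w1 + w2) / 2)
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  attr(z, "ks_statistic") <- unname(ks$statistic)
  attr(z, "ks_p") <- ks$p.value
  z
}
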