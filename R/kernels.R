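#' Anisotropic Laplacian-of-Gaussian profile kernel
#'
#' The bouton-detection filter: an in-plane (xy) Laplacian of Gaussian of
#' size `R_xy` combined with a normalized axial Gaussian of size `R_z`,
#'
#' \deqn{\frac{4 e^{-(dx^2+dy^2)/R_{xy}^2}}{\pi R_{xy}^4}
#'       \left(1 - \frac{dx^2+dy^2}{R_{xy}^2}\right)
#'       \frac{e^{-dz^2/R_z^2}}{\sqrt{\pi} R_z}.}
#'
#' The in-plane part has zero mean (it sharpens bouton boundaries by
#' suppressing intensity immediately around a blob); the polynomial crosses
#' zero at lateral radius `R_xy`.
#'
#' @param dx,dy,dz offsets from the kernel center, um (vectorized).
#' @param R_xy,R_z lateral and axial sizes, um, both positive.
#' @return Kernel values.
#' @export
log_xy_kernel <- function(dx, dy, dz, R_xy, R_z) {
  stopifnot(R_xy > 0, R_z > 0)
  r2 <- (dx^2 + dy^2) / R_xy^2
  4 * exp(-r2) / (pi * R_xy^4) * (1 - r2) *
    exp(-(dz / R_z)^2) / (sqrt(pi) * R_z)
}

#' Isotropic Gaussian profile kernel
#'
#' The shaft-intensity filter, a unit-integral 3D Gaussian
#' \eqn{e^{-\|d\|^2/R^2} / (\pi^{3/2} R^3)}.
#'
#' @param dx,dy,dz offsets from the kernel center, um (vectorized).
#' @param R size, um, positive.
#' @return Kernel values.
#' @export
gaussian_kernel <- function(dx, dy, dz, R) {
  stopifnot(R > 0)
  exp(-(dx^2 + dy^2 + dz^2) / R^2) / (pi^1.5 * R^3)
}

# Negative 3D Laplacian-of-Gaussian kernel used by the trace-optimization
# fitness: exp(-u/(2R^2)) / ((2pi)^{3/2} R^3) * (1 - u/(3R^2)), u = ||d||^2.
# Returns value and, optionally, derivatives wrt u for gradient/Hessian.
opt_kernel <- function(u, R, deriv = 0L) {
  c0 <- 1 / ((2 * pi)^1.5 * R^3)
  e <- exp(-u / (2 * R^2))
  if (deriv == 0L) return(c0 * e * (1 - u / (3 * R^2)))
  if (deriv == 1L) return(c0 * e * (u / (6 * R^4) - 5 / (6 * R^2)))
  # second derivative wrt u
  c0 * e * (-(u / (6 * R^4) - 5 / (6 * R^2)) / (2 * R^2) + 1 / (6 * R^4))
}
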