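# Trace optimization: refine a manual centerline against the image by
# maximizing an intensity + stiffness fitness with a safeguarded Newton
# method.

# Per-node intensity term of the fitness: convolution of the image with the
# negative 3D LoG kernel of size R (um) evaluated at the node position.
# Returns value, and optionally gradient (3) and Hessian (3x3) wrt the node.
node_conv <- function(stack, p, R, cutoff = 4, deriv = FALSE) {
  v <- stack$voxel_size
  d <- dim(stack$values)
  h <- cutoff * R
  ix <- axis_window(p[1], h, d[1], v[1])
  iy <- axis_window(p[2], h, d[2], v[2])
  iz <- axis_window(p[3], h, d[3], v[3])
  zero <- list(value = 0, grad = numeric(3), hess = matrix(0, 3, 3))
  if (!length(ix) || !length(iy) || !length(iz)) return(zero)
  dx <- axis_centers(d[1], v[1])[ix] - p[1]
  dy <- axis_centers(d[2], v[2])[iy] - p[2]
  dz <- axis_centers(d[3], v[3])[iz] - p[3]
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  DX <- array(dx, c(nx, ny, nz))
  DY <- array(rep(dy, each = nx), c(nx, ny, nz))
  DZ <- array(rep(dz, each = nx * ny), c(nx, ny, nz))
  u <- DX^2 + DY^2 + DZ^2
  keep <- u <= h^2
  I <- stack$values[ix, iy, iz, drop = FALSE]
  Ik <- I[keep]
  if (!length(Ik)) return(zero)
  uk <- u[keep]
  val <- sum(Ik * opt_kernel(uk, R))
  if (!deriv) return(list(value = val))
  # Delta = p - l  =>  d(u)/dp = 2*Delta = -2*(DX,DY,DZ)
  Dx <- -DX[keep]; Dy <- -DY[keep]; Dz <- -DZ[keep]
  k1 <- opt_kernel(uk, R, deriv = 1L)
  k2 <- opt_kernel(uk, R, deriv = 2L)
  g <- 2 * c(sum(Ik * k1 * Dx), sum(Ik * k1 * Dy), sum(Ik * k1 * Dz))
  s1 <- 2 * sum(Ik * k1)
  H <- diag(s1, 3) + 4 * matrix(c(
    sum(Ik * k2 * Dx * Dx), sum(Ik * k2 * Dx * Dy), sum(Ik * k2 * Dx * Dz),
    sum(Ik * k2 * Dy * Dx), sum(Ik * k2 * Dy * Dy), sum(Ik * k2 * Dy * Dz),
    sum(Ik * k2 * Dz * Dx), sum(Ik * k2 * Dz * Dy), sum(Ik * k2 * Dz * Dz)),
    3, 3)
  list(value = val, grad = g, hess = H)
}

fitness_parts <- function(stack, nodes, R, lambda, alpha, cutoff = 4,
                          deriv = FALSE) {
  n <- nrow(nodes)
  conv_val <- 0
  if (deriv) {
    g <- matrix(0, n, 3)
    Hblocks <- vector("list", n)
  }
  for (k in seq_len(n)) {
    nc <- node_conv(stack, nodes[k, ], R, cutoff, deriv)
    conv_val <- conv_val + nc$value
    if (deriv) { g[k, ] <- nc$grad; Hblocks[[k]] <- nc$hess }
  }
  # stiffness penalty on discrete curvature: deviation of each interior
  # node from the midpoint of its neighbors (a straight, equally spaced
  # trace is penalty-free; large alpha drives nodes collinear)
  if (n > 2) {
    D <- matrix(0, n - 2L, n)
    for (k in seq_len(n - 2L)) D[k, k:(k + 2L)] <- c(-0.5, 1, -0.5)
    curv <- D %*% nodes
    pen <- (alpha * lambda / 2) * sum(curv^2)
  } else {
    D <- matrix(0, 0L, n)
    curv <- matrix(0, 0L, 3)
    pen <- 0
  }
  F <- conv_val / lambda - pen
  if (!deriv) return(list(fitness = F))
  gp <- -alpha * lambda * (t(D) %*% curv)
  G <- g / lambda + gp
  # Hessian: block diagonal from the intensity term plus the curvature
  # operator -alpha*lambda * (D'D x I3)
  DtD <- crossprod(D)
  H <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(n)) {
    idx <- (3 * (k - 1) + 1):(3 * k)
    H[idx, idx] <- Hblocks[[k]] / lambda - alpha * lambda * DtD[k, k] * diag(3)
    for (k2 in seq_len(n)) {
      if (k2 != k && DtD[k, k2] != 0) {
        jdx <- (3 * (k2 - 1) + 1):(3 * k2)
        H[idx, jdx] <- H[idx, jdx] - alpha * lambda * DtD[k, k2] * diag(3)
      }
    }
  }
  list(fitness = F, grad = as.vector(t(G)), hess = H)
}

#' Trace fitness
#'
#' Fitness of a trace layout against the image: image intensity integrated
#' along the trace through a negative 3D Laplacian-of-Gaussian kernel of
#' size `R_opt`, minus a stiffness penalty on the discrete curvature of
#' the node chain,
#'
#' \deqn{F = \tfrac{1}{\lambda}\sum_k \sum_m I(l_m) K(r_k - l_m)
#'   - \tfrac{\alpha\lambda}{2}\sum_k
#'     \|r_k - \tfrac{r_{k-1}+r_{k+1}}{2}\|^2}
#'
#' with \eqn{K(d) = e^{-\|d\|^2/2R^2}/((2\pi)^{3/2}R^3)\,
#' (1 - \|d\|^2/3R^2)}; the stiffness sum runs over interior nodes, so a
#' straight, equally spaced trace incurs no penalty and large
#' `stiffness_alpha` drives the trace toward a straight line rather than
#' collapsing it. The voxel sum is truncated at `cutoff * R`.
#' `R_opt` is given in voxels and converted with the lateral voxel size;
#' distances are physical (um) so z keeps its anisotropy.
#'
#' @param stack an [image_stack].
#' @param trace an [axon_trace].
#' @param config a [pipeline_config] (fields `R_opt`, `lambda_opt`,
#'   `stiffness_alpha`, `cutoff`).
#' @return Fitness value (scalar).
#' @export
trace_fitness <- function(stack, trace, config = pipeline_config()) {
  stopifnot(inherits(stack, "image_stack"), inherits(trace, "axon_trace"))
  R <- config$R_opt * mean(stack$voxel_size[1:2])
  fitness_parts(stack, trace$nodes, R, config$lambda_opt,
                config$stiffness_alpha, config$cutoff)$fitness
}

#' Optimize a trace against the image
#'
#' Maximizes [trace_fitness] over all node positions simultaneously with a
#' damped Newton method: when the Hessian is negative definite the Newton
#' step is taken, otherwise the method falls back to gradient ascent; both
#' use backtracking so accepted iterations never decrease the fitness.
#' Iteration stops when the relative fitness change falls below
#' `config$opt_tol` (default 1e-6) or after `config$opt_max_iter` steps.
#' Endpoints are free.
#'
#' @inheritParams trace_fitness
#' @param verbose print per-iteration fitness.
#' @return The optimized [axon_trace] (same node count, arc length
#'   recomputed), with attributes `fitness_log` (data.frame of iteration,
#'   fitness, step kind) and `termination` (`"converged"` or
#'   `"max_iter"`).
#' @export
optimize_trace <- function(stack, trace, config = pipeline_config(),
                           verbose = FALSE) {
  stopifnot(inherits(stack, "image_stack"), inherits(trace, "axon_trace"))
  R <- config$R_opt * mean(stack$voxel_size[1:2])
  lambda <- config$lambda_opt
  alpha <- config$stiffness_alpha
  nodes <- trace$nodes
  n <- nrow(nodes)
  fp <- fitness_parts(stack, nodes, R, lambda, alpha, config$cutoff,
                      deriv = TRUE)
  if (!is.finite(fp$fitness)) stop("non-finite fitness at initial trace")
  log_rows <- list(data.frame(iter = 0L, fitness = fp$fitness,
                              step = "init"))
  termination <- "max_iter"
  for (it in seq_len(config$opt_max_iter)) {
    dir <- NULL
    kind <- "newton"
    ch <- tryCatch(chol(-fp$hess), error = function(e) NULL)
    if (is.null(ch)) {
      # Hessian not negative definite (e.g. the stiffness operator is
      # singular along rigid motions): damp it until it is
      scale <- max(abs(diag(fp$hess)), 1e-8)
      for (delta in scale * 10^c(-8, -6, -4, -2, 0, 2)) {
        ch <- tryCatch(chol(-fp$hess + delta * diag(nrow(fp$hess))),
                       error = function(e) NULL)
        if (!is.null(ch)) { kind <- "damped-newton"; break }
      }
    }
    if (!is.null(ch)) {
      dir <- backsolve(ch, forwardsolve(t(ch), fp$grad))
    } else {
      kind <- "gradient"
      gn <- sqrt(sum(fp$grad^2))
      if (gn == 0) { termination <- "converged"; break }
      dir <- fp$grad / gn * mean(stack$voxel_size[1:2])
    }
    # backtracking line search on the ascent direction
    tau <- 1
    improved <- FALSE
    for (bt in 1:30) {
      cand <- nodes + tau * matrix(dir, n, 3, byrow = TRUE)
      Fc <- fitness_parts(stack, cand, R, lambda, alpha,
                          config$cutoff)$fitness
      if (is.finite(Fc) && Fc > fp$fitness) { improved <- TRUE; break }
      tau <- tau / 2
    }
    if (!improved) { termination <- "converged"; break }
    rel <- abs(Fc - fp$fitness) / max(abs(fp$fitness), 1e-12)
    nodes <- cand
    fp <- fitness_parts(stack, nodes, R, lambda, alpha, config$cutoff,
                        deriv = TRUE)
    if (!is.finite(fp$fitness))
      stop("non-finite fitness during optimization (NaN intensity?)")
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(iter = it, fitness = fp$fitness, step = kind)
    if (verbose)
      message(sprintf("iter %3d  F = %.8g  (%s, tau = %g)",
                      it, fp$fitness, kind, tau))
    if (rel < config$opt_tol) { termination <- "converged"; break }
  }
  out <- axon_trace(nodes, axon_id = trace$axon_id,
                    session_id = trace$session_id,
                    exclusions = trace$exclusions)
  attr(out, "fitness_log") <- do.call(rbind, log_rows)
  attr(out, "termination") <- termination
  out
}
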