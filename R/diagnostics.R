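## Validity diagnostics for the linearization: Lyapunov exponents of the
## time-T_s flow map, contraction-mapping checks, exact second-order error
## indicators, and input-sensitivity drift between fixed points.

# Integrate the flow map Phi over [0, T_s] together with its Jacobian
# M(T_s) = d Phi(x0) / d x0 via the variational matrix ODE dM/dt = J(x(t)) M.
# For a linear time-invariant model the map is exact: M = expm(A T_s).
mat_exp <- function(M) as.matrix(Matrix::expm(M))

flow_map_jacobian <- function(model, x0, u, T_s, rtol = 1e-10, atol = 1e-12) {
  if (T_s <= 0) stop("contract error: T_s must be positive")
  n <- model$n_species
  if (inherits(model, "linear_system")) {
    M <- mat_exp(model$A * T_s)
    f0 <- evaluate_rhs(model, x0, u)
    # x(T) = x0 + A^{-1} (e^{AT} - I) f(x0)  for constant A
    xT <- tryCatch(x0 + drop(solve(model$A, (M - diag(n)) %*% f0)),
                   error = function(e) NULL)
    if (is.null(xT)) { # singular A: fall back to integration of the state only
      xT <- as.numeric(utils::tail(simulate_trajectory(model, u, x0, c(0, T_s),
                                                       rtol, atol), 1))[-1]
    }
    return(list(x_T = xT, M = M))
  }
  y0 <- c(x0, as.numeric(diag(n)))
  func <- function(t, y, parms) {
    x <- y[seq_len(n)]
    M <- matrix(y[-seq_len(n)], n, n)
    J <- state_jacobian(model, x)
    list(c(evaluate_rhs(model, x, u), as.numeric(J %*% M)))
  }
  sol <- deSolve::ode(y = y0, times = c(0, T_s), func = func, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("numerical error: variational integration failed")
  yT <- as.numeric(sol[2, -1])
  list(x_T = yT[seq_len(n)], M = matrix(yT[-seq_len(n)], n, n))
}

default_sampling_period <- function(model, x) {
  ev <- eigen(state_jacobian(model, x), only.values = TRUE)$values
  rho <- max(abs(ev))
  if (rho <= 0) 1 else 0.1 / rho
}

#' Local Lyapunov exponent of the sampled flow map
#'
#' The flow over one sampling period \eqn{T_s} defines a discrete map
#' \eqn{\Phi}; the local Lyapunov exponent at `x` in direction `y` is the
#' per-unit-time log growth of an infinitesimal separation,
#' \eqn{\ln \|J(\Phi, x)\, y\| / T_s}, with the map Jacobian obtained by
#' variational integration (exactly, via the matrix exponential, for linear
#' models). Negative values mean nearby trajectories converge locally.
#'
#' @param model a [reaction_network()] or [linear_system()].
#' @param x state at which the exponent is evaluated.
#' @param y unit direction vector.
#' @param u constant input held during the sampling period.
#' @param T_s sampling period; `NULL` picks `0.1 /` spectral radius of the
#'   Jacobian at `x`.
#' @return exponent in 1/time units.
#' @export
local_lyapunov_exponent <- function(model, x, y, u, T_s = NULL) {
  if (abs(sqrt(sum(y^2)) - 1) > 1e-8) stop("direction y must have unit norm")
  if (is.null(T_s)) T_s <- default_sampling_period(model, x)
  fm <- flow_map_jacobian(model, x, u, T_s)
  log(sqrt(sum((fm$M %*% y)^2))) / T_s
}

#' Global Lyapunov exponent estimate along a trajectory
#'
#' Propagates a separation direction through the flow-map Jacobian at
#' successive trajectory points \eqn{x_0, x_1, \dots} and averages the
#' per-step log growth — the discrete estimate of the global exponent. For a
#' trajectory converging to a stable fixed point the tail of the local
#' exponents approaches an eigen-direction decay rate.
#'
#' @inheritParams local_lyapunov_exponent
#' @param x0 trajectory start.
#' @param y0 initial unit direction.
#' @param n_steps number of sampling periods to average over.
#' @return list with `lambda` (the average), `local` (per-step exponents)
#'   and `T_s`.
#' @export
global_lyapunov_estimate <- function(model, x0, u, y0, T_s = NULL, n_steps = 20L) {
  if (abs(sqrt(sum(y0^2)) - 1) > 1e-8) stop("direction y0 must have unit norm")
  if (is.null(T_s)) T_s <- default_sampling_period(model, x0)
  x <- x0; y <- y0
  local <- numeric(n_steps)
  scale0 <- max(1, max(abs(x0)))
  for (k in seq_len(n_steps)) {
    fm <- flow_map_jacobian(model, x, u, T_s)
    w <- drop(fm$M %*% y)
    nw <- sqrt(sum(w^2))
    local[k] <- log(nw) / T_s
    y <- w / nw
    x <- fm$x_T
    if (max(abs(x)) > 1e9 * scale0)
      stop("instability: trajectory diverged during Lyapunov estimation")
  }
  list(lambda = mean(local), local = local, T_s = T_s)
}

#' Contraction check of the sampled flow map over a region
#'
#' At each sample point, computes the spectral norm of the flow-map Jacobian
#' over one sampling period; `c_max` is the maximum over samples. If
#' `c_max < 1` the map shrinks separations everywhere sampled — the
#' sufficient (Banach) condition for a unique fixed point in the region.
#' The spectral norm can exceed the eigenvalue-based decay factor for
#' non-normal Jacobians, so the check is conservative.
#'
#' @inheritParams local_lyapunov_exponent
#' @param region_samples list of nonnegative state vectors covering the
#'   region of interest.
#' @return list with `is_contraction`, `c_max`, `c_values` and `margin`
#'   (`1 - c_max`).
#' @export
contraction_check <- function(model, region_samples, u, T_s = NULL) {
  stopifnot(length(region_samples) >= 1)
  if (is.null(T_s)) T_s <- default_sampling_period(model, region_samples[[1]])
  cv <- vapply(region_samples, function(x) {
    fm <- flow_map_jacobian(model, x, u, T_s)
    max(svd(fm$M)$d)
  }, numeric(1))
  c_max <- max(cv)
  list(is_contraction = c_max < 1, c_max = c_max, c_values = cv,
       margin = 1 - c_max, T_s = T_s)
}

#' Second-order (Hessian) error indicator
#'
#' Magnitude of the first Taylor term discarded by the linearization,
#' \eqn{\tfrac12 dx^T (\partial^2 f/\partial x^2) dx}, evaluated per
#' component by the symmetric second difference
#' \eqn{[f(x + dx) + f(x - dx) - 2 f(x)] / 2}. For mass-action kinetics (at
#' most bimolecular, hence a bilinear right-hand side) third derivatives
#' vanish and the second difference is exact, not an approximation. Large
#' values at the anchor flag perturbations for which the linear prediction
#' will drift.
#'
#' @inheritParams local_lyapunov_exponent
#' @param x_anchor expansion point.
#' @param dx state deviation of interest.
#' @return list with `norm` (Euclidean norm of the term, conc/time) and
#'   `components` (the per-state values).
#' @export
hessian_error_indicator <- function(model, x_anchor, dx, u = NULL) {
  if (is.null(u)) u <- numeric(model$n_inputs)
  h <- (evaluate_rhs(model, x_anchor + dx, u) +
          evaluate_rhs(model, x_anchor - dx, u) -
          2 * evaluate_rhs(model, x_anchor, u)) / 2
  list(norm = sqrt(sum(h^2)), components = h)
}

#' Compare steady-state input sensitivities at two fixed points
#'
#' The steady-state sensitivity to inputs is
#' \eqn{S(x) = -(\partial f/\partial x)^{-1} B}. A large difference between
#' \eqn{S} at the linearization anchor and at the post-perturbation fixed
#' point means the two models respond differently to further input changes —
#' a warning sign for the validity of the frozen linearization.
#'
#' @inheritParams local_lyapunov_exponent
#' @param x_anchor linearization anchor state.
#' @param x_new post-perturbation fixed point.
#' @return list with `diff_norm` (spectral norm of the sensitivity
#'   difference), `rel_change` (relative to the anchor sensitivity norm),
#'   and the two sensitivity matrices.
#' @export
input_sensitivity_compare <- function(model, x_anchor, x_new) {
  B <- input_jacobian(model)
  sens <- function(x) {
    J <- state_jacobian(model, x)
    if (kappa(J, exact = FALSE) > 1e12)
      stop("singularity error: state Jacobian is singular or ill-conditioned")
    -solve(J, B)
  }
  S0 <- sens(x_anchor); S1 <- sens(x_new)
  spec <- function(M) if (length(M)) max(svd(M)$d) else 0
  dn <- spec(S1 - S0)
  list(diff_norm = dn, rel_change = dn / max(spec(S0), .Machine$double.eps),
       S_anchor = S0, S_new = S1)
}
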