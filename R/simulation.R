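## Forward simulation: stiff integration with analytic Jacobians, steady-state
## detection + Newton refinement, and the augmented agreement system that
## co-evolves the linearized deviation state with the nonlinear state.

desolve_funcs <- function(model, u) {
  list(
    func = function(t, y, parms) list(evaluate_rhs(model, y, u)),
    jacfunc = function(t, y, parms) state_jacobian(model, y)
  )
}

steady_residual <- function(f, x, tol_ss) {
  max(abs(f)) < tol_ss * (1 + max(abs(x)))
}

# Damped Newton iteration on f(x, u) = 0 starting near a root.
newton_refine <- function(model, x, u, tol = 1e-13, max_iter = 50L) {
  f <- evaluate_rhs(model, x, u)
  for (it in seq_len(max_iter)) {
    res <- max(abs(f))
    if (res < tol * (1 + max(abs(x)))) break
    J <- state_jacobian(model, x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      x_new <- x + lambda * step
      f_new <- evaluate_rhs(model, x_new, u)
      if (max(abs(f_new)) < res || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (max(abs(f_new)) >= res) break
    x <- x_new; f <- f_new
  }
  list(x = x, residual = max(abs(f)))
}

#' Simulate a model to steady state under a constant input
#'
#' Integrates \eqn{dx/dt = f(x, u)} with a stiff variable-step method and the
#' analytic Jacobian, over doubling time horizons, until the residual
#' criterion \eqn{\|f\|_\infty < \mathrm{tol_{ss}} (1 + \|x\|_\infty)} holds;
#' the located point is then polished by a damped Newton iteration on
#' \eqn{f(x, u) = 0}, and tiny negative entries (integration round-off) are
#' clipped to zero.
#'
#' @param model a [reaction_network()] or [linear_system()].
#' @param u constant (step-like) input vector.
#' @param x0 initial state; defaults to the origin.
#' @param tol_ss steady-state residual tolerance (relative to state scale).
#' @param t_max maximum integration horizon before declaring non-convergence;
#'   reaching it usually signals an unstable or oscillatory model.
#' @param rtol,atol integrator tolerances.
#' @return object of class `steady_state` with fields `x_ss`, `u_bf`,
#'   `residual_norm` (\eqn{\|f\|_\infty} at the returned point),
#'   `t_converged` and `method`.
#' @export
simulate_to_steady_state <- function(model, u, x0 = NULL, tol_ss = 1e-9,
                                     t_max = 1e7, rtol = 1e-8, atol = 1e-10) {
  n <- model$n_species
  if (is.null(x0)) x0 <- numeric(n)
  check_u(model, u)
  if (length(x0) != n) stop("x0 has length ", length(x0), ", expected ", n)
  fns <- desolve_funcs(model, u)
  x <- x0
  scale0 <- max(1, max(abs(x0)), if (length(u)) max(abs(u)) else 0)
  t_now <- 0; t_chunk <- 1
  converged <- FALSE
  while (t_now < t_max) {
    sol <- deSolve::ode(y = x, times = c(0, t_chunk), func = fns$func,
                        parms = NULL, jacfunc = fns$jacfunc, jactype = "fullusr",
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) stop("numerical error: stiff integration failed")
    x <- as.numeric(sol[nrow(sol), -1])
    t_now <- t_now + t_chunk
    if (max(abs(x)) > 1e9 * scale0)
      stop("instability: trajectory norm exceeded the divergence bound")
    if (steady_residual(evaluate_rhs(model, x, u), x, tol_ss)) { converged <- TRUE; break }
    t_chunk <- t_chunk * 2
  }
  if (!converged)
    stop("non-convergence: no steady state reached within t_max = ", t_max,
         " (model may be unstable or oscillatory)")
  ref <- newton_refine(model, x, u)
  x <- ref$x
  if (inherits(model, "reaction_network")) {
    # concentrations cannot be negative; round-off excursions are clipped
    if (any(x < -100 * atol))
      warning("steady state had negative entries below -100*atol; clipped to 0")
    x[x < 0] <- 0
  }
  structure(list(x_ss = stats::setNames(x, model$species), u_bf = u,
                 residual_norm = max(abs(evaluate_rhs(model, x, u))),
                 t_converged = t_now, method = "integrate+newton",
                 tol_ss = tol_ss),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("steady_state:", length(x$x_ss), "states; residual",
      format(x$residual_norm, digits = 3), "after t =", x$t_converged, "\n")
  invisible(x)
}

#' Simulate a trajectory on a fixed time grid
#'
#' Dense forward integration of the model under a constant input, with the
#' analytic Jacobian supplied to the stiff solver.
#'
#' @inheritParams simulate_to_steady_state
#' @param t_grid increasing vector of output times (first entry is the
#'   initial time).
#' @return data.frame with a `time` column and one column per species.
#' @export
simulate_trajectory <- function(model, u, x0, t_grid, rtol = 1e-8, atol = 1e-10) {
  check_u(model, u)
  if (length(x0) != model$n_species) stop("x0 dimension mismatch")
  fns <- desolve_funcs(model, u)
  sol <- deSolve::ode(y = x0, times = t_grid, func = fns$func, parms = NULL,
                      jacfunc = fns$jacfunc, jactype = "fullusr",
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("numerical error: integration failed")
  out <- as.data.frame(sol)
  names(out) <- c("time", model$species)
  out
}

#' Build the augmented agreement system
#'
#' Stacks the linearized deviation dynamics on top of the nonlinear dynamics
#' into one 2n-state autonomous system,
#' \deqn{d/dt [x_{dev}; x_{nonlin}] = [A x_{dev} + B (u - u_{bf});\; f(x_{nonlin}, u)],}
#' whose Jacobian is block diagonal. Simulating it from
#' \eqn{[0; x_{ss}]} makes the linearization error
#' \eqn{e(t) = x_{nonlin}(t) - x_{dev}(t) - x_{ss}} directly observable.
#'
#' @param network the nonlinear model.
#' @param linmodel a [linearize()] result anchored at a steady state of
#'   `network`.
#' @return object of class `agreement_system`.
#' @export
build_agreement_system <- function(network, linmodel) {
  stopifnot(inherits(linmodel, "linear_model"))
  if (network$n_species != nrow(linmodel$A))
    stop("contract error: network and linear model dimensions differ")
  if (network$n_inputs != ncol(linmodel$B))
    stop("contract error: input dimensions differ")
  structure(list(network = network, lin = linmodel, n = network$n_species),
            class = "agreement_system")
}

agreement_rhs <- function(ag, y, u) {
  n <- ag$n
  x_dev <- y[seq_len(n)]; x_nl <- y[n + seq_len(n)]
  du <- u - ag$lin$u_bf
  c(unname(drop(ag$lin$A %*% x_dev) + drop(ag$lin$B %*% du)),
    evaluate_rhs(ag$network, x_nl, u))
}

agreement_jac <- function(ag, y) {
  n <- ag$n
  J <- matrix(0, 2 * n, 2 * n)
  J[seq_len(n), seq_len(n)] <- ag$lin$A
  J[n + seq_len(n), n + seq_len(n)] <- state_jacobian(ag$network, y[n + seq_len(n)])
  J
}

#' Co-simulate the linearized and nonlinear models
#'
#' Integrates the [build_agreement_system()] from
#' \eqn{x_{agreement}(0) = [0; x_{ss}]} under a constant input until the joint
#' steady state, then polishes the steady-state slices: the deviation block by
#' its exact linear solve, the nonlinear block by Newton iteration. The error
#' trajectory \eqn{e(t) = x_{nonlin} - x_{dev} - x_{ss}} starts at zero by
#' construction.
#'
#' @param agreement an `agreement_system`.
#' @param u constant input vector applied at `t = 0`.
#' @param t_max maximum horizon.
#' @param tol_ss joint steady-state residual tolerance.
#' @param n_times number of output times recorded per integration chunk.
#' @param rtol,atol integrator tolerances.
#' @return object of class `agreement_result`: `time`, matrices `x_dev`,
#'   `x_nonlin`, `e` (rows = times), steady-state slices `x_dev_ss`,
#'   `x_nonlin_ss`, `e_ss`, and the anchor `x_ss`.
#' @export
simulate_agreement <- function(agreement, u, t_max = 1e7, tol_ss = 1e-9,
                               n_times = 41L, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(agreement, "agreement_system"))
  n <- agreement$n
  x_ss <- as.numeric(agreement$lin$x_ss)
  check_u(agreement$network, u)
  y <- c(numeric(n), x_ss)
  func <- function(t, y, parms) list(agreement_rhs(agreement, y, u))
  jacf <- function(t, y, parms) agreement_jac(agreement, y)
  times <- numeric(); states <- NULL
  t_now <- 0; t_chunk <- 1; converged <- FALSE
  scale0 <- max(1, max(abs(x_ss)), if (length(u)) max(abs(u)) else 0)
  while (t_now < t_max) {
    tg <- seq(0, t_chunk, length.out = n_times)
    sol <- deSolve::ode(y = y, times = tg, func = func, parms = NULL,
                        jacfunc = jacf, jactype = "fullusr",
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) stop("numerical error: agreement integration failed")
    keep <- if (t_now == 0) seq_len(nrow(sol)) else -1L
    times <- c(times, t_now + sol[keep, 1])
    states <- rbind(states, sol[keep, -1, drop = FALSE])
    y <- as.numeric(sol[nrow(sol), -1])
    t_now <- t_now + t_chunk
    if (max(abs(y)) > 1e9 * scale0)
      stop("instability: agreement trajectory exceeded the divergence bound")
    if (steady_residual(agreement_rhs(agreement, y, u), y, tol_ss)) {
      converged <- TRUE; break
    }
    t_chunk <- t_chunk * 2
  }
  if (!converged)
    stop("non-convergence: agreement system did not reach steady state")

  # steady-state polish: exact linear solve for the deviation block,
  # damped Newton for the nonlinear block
  du <- u - agreement$lin$u_bf
  x_dev_ss <- drop(solve(agreement$lin$A, -agreement$lin$B %*% du))
  x_nl_ss <- newton_refine(agreement$network, y[n + seq_len(n)], u)$x

  x_dev <- states[, seq_len(n), drop = FALSE]
  x_nl <- states[, n + seq_len(n), drop = FALSE]
  e_t <- x_nl - x_dev - matrix(x_ss, nrow(x_nl), n, byrow = TRUE)
  colnames(x_dev) <- colnames(x_nl) <- colnames(e_t) <- agreement$network$species
  structure(list(time = times, x_dev = x_dev, x_nonlin = x_nl, e = e_t,
                 x_dev_ss = stats::setNames(x_dev_ss, agreement$network$species),
                 x_nonlin_ss = stats::setNames(x_nl_ss, agreement$network$species),
                 e_ss = stats::setNames(x_nl_ss - x_dev_ss - x_ss,
                                        agreement$network$species),
                 x_ss = stats::setNames(x_ss, agreement$network$species),
                 u = u),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("agreement_result:", ncol(x$e), "states,", length(x$time), "time points;",
      "||e_ss||_inf =", format(max(abs(x$e_ss)), digits = 4), "\n")
  invisible(x)
}
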