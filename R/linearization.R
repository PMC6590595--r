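#' Linearize a model around a steady state
#'
#' First-order Taylor expansion of the dynamics at the anchor
#' \eqn{(x_{ss}, u_{bf})}: all second- and higher-order state terms are
#' discarded, giving the deviation model
#' \eqn{\dot x_{dev} = A x_{dev} + B (u - u_{bf})} with
#' \eqn{A = \partial f/\partial x} and \eqn{B = \partial f/\partial u} at the
#' anchor. For mass-action networks the expansion has no input error terms
#' (see [check_linearity_conditions()]). Eigenvalues of `A` are cached along
#' with stability and hyperbolicity flags.
#'
#' @param model a [reaction_network()] or [linear_system()].
#' @param ss a [simulate_to_steady_state()] result (the anchor).
#' @return object of class `linear_model` with fields `A`, `B`, `x_ss`,
#'   `u_bf`, `eigenvalues`, `stable`, `hyperbolic`.
#' @export
linearize <- function(model, ss) {
  stopifnot(inherits(ss, "steady_state"))
  if (ss$residual_norm >= ss$tol_ss * (1 + max(abs(ss$x_ss))) * 10)
    stop("precondition error: anchor point does not satisfy the steady-state tolerance")
  A <- state_jacobian(model, as.numeric(ss$x_ss))
  B <- input_jacobian(model)
  ev <- eigen(A, only.values = TRUE)$values
  hb <- check_hyperbolic_eigen(ev)
  structure(list(A = A, B = B, x_ss = ss$x_ss, u_bf = ss$u_bf,
                 eigenvalues = ev, stable = hb$stable, hyperbolic = hb$hyperbolic),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat("linear_model:", nrow(x$A), "states,", ncol(x$B), "inputs;",
      if (x$stable) "stable" else "NOT stable", "/",
      if (x$hyperbolic) "hyperbolic" else "NOT hyperbolic", "anchor\n")
  invisible(x)
}

check_hyperbolic_eigen <- function(ev, tol_re = NULL) {
  rho <- max(abs(ev))
  if (is.null(tol_re)) tol_re <- 1e-8 * max(rho, .Machine$double.eps)
  list(hyperbolic = min(abs(Re(ev))) > tol_re,
       stable = max(Re(ev)) < -tol_re,
       eigenvalues = ev, tol_re = tol_re)
}

#' Hyperbolicity and stability of a linearization anchor
#'
#' A fixed point is hyperbolic when no Jacobian eigenvalue has zero real
#' part — the precondition under which the linearization shares the local
#' qualitative behavior of the nonlinear model (Hartman–Grobman). Stability
#' additionally requires every real part to be negative.
#'
#' @param lin a [linearize()] result, or a square matrix taken as the
#'   Jacobian itself.
#' @param tol_re real-part tolerance; default `1e-8` times the spectral
#'   radius.
#' @return list with `hyperbolic`, `stable`, `eigenvalues`, `tol_re`.
#' @export
check_hyperbolic <- function(lin, tol_re = NULL) {
  ev <- if (inherits(lin, "linear_model")) lin$eigenvalues
        else if (is.matrix(lin)) eigen(lin, only.values = TRUE)$values
        else stop("lin must be a linear_model or a square matrix")
  check_hyperbolic_eigen(ev, tol_re)
}

#' Predict the post-perturbation steady state of the linearized model
#'
#' For a step-like input with final value `u_final`, the linear deviation
#' model settles at \eqn{x_{dev,ss} = -A^{-1} B (u_{final} - u_{bf})}; the
#' predicted state is \eqn{x_{ss} + x_{dev,ss}}, obtained with exactly one
#' linear solve and no integration.
#'
#' @param lin a [linearize()] result with invertible, well-conditioned `A`.
#' @param u_final final value of the input step.
#' @param clip clip negative entries of the prediction to zero (see
#'   [clip_nonnegative()]).
#' @return predicted steady-state vector.
#' @export
linear_steady_state <- function(lin, u_final, clip = FALSE) {
  stopifnot(inherits(lin, "linear_model"))
  if (length(u_final) != ncol(lin$B)) stop("u_final dimension mismatch")
  if (!is.finite(kappa(lin$A, exact = FALSE)) || kappa(lin$A, exact = FALSE) > 1e12)
    stop("singularity error: state matrix is singular or ill-conditioned (non-hyperbolic anchor)")
  x_dev <- drop(solve(lin$A, -lin$B %*% (u_final - lin$u_bf)))
  out <- as.numeric(lin$x_ss) + x_dev
  names(out) <- names(lin$x_ss)
  if (clip) clip_nonnegative(out) else out
}

#' Clip a state prediction to the nonnegative orthant
#'
#' Negative concentrations have no physical meaning; linear predictions are
#' adjusted componentwise to `max(x, 0)`. Idempotent.
#'
#' @param x_pred numeric vector.
#' @return clipped vector.
#' @export
clip_nonnegative <- function(x_pred) pmax(x_pred, 0)

#' Piecewise relinearized steady-state prediction
#'
#' Advances the model by exact linear steps of length `dt`, recomputing the
#' Jacobian at the start of every step:
#' \eqn{x_{k+1} = x_k + A_k^{-1} (e^{A_k dt} - I) f(x_k, u)}. As
#' \eqn{dt \to 0} the scheme tracks the nonlinear trajectory and its limit is
#' the nonlinear steady state; when the Jacobian is constant (a linear model)
#' a single large step reproduces the one-solve prediction of
#' [linear_steady_state()]. `dt = Inf` turns each step into a full Newton
#' step.
#'
#' @param model the nonlinear model.
#' @param u_final constant input.
#' @param ss0 starting [simulate_to_steady_state()] anchor.
#' @param dt time increment between relinearizations (may be `Inf`).
#' @param tol stop when \eqn{\|x_{k+1} - x_k\|_\infty < } `tol`.
#' @param max_steps iteration cap.
#' @param keep_path also return the matrix of iterates (row `k` is the state
#'   after `k` increments, i.e. at time `k * dt`), for comparison against the
#'   nonlinear trajectory.
#' @return list with `x` (the predicted steady state), `n_steps`, `converged`,
#'   `dt`, and optionally `path`.
#' @export
iterative_relinearization <- function(model, u_final, ss0, dt = 0.05,
                                      tol = 1e-10, max_steps = 100000L,
                                      keep_path = FALSE) {
  stopifnot(inherits(ss0, "steady_state"))
  x <- as.numeric(ss0$x_ss)
  n <- length(x)
  path <- if (keep_path) list() else NULL
  for (k in seq_len(max_steps)) {
    f <- evaluate_rhs(model, x, u_final)
    A <- state_jacobian(model, x)
    step <- if (is.infinite(dt)) {
      drop(solve(A, -f))
    } else {
      drop(solve(A, (mat_exp(A * dt) - diag(n)) %*% f))
    }
    x_new <- x + step
    if (keep_path) path[[k]] <- x_new
    if (max(abs(x_new - x)) < tol) {
      return(list(x = stats::setNames(x_new, model$species), n_steps = k,
                  converged = TRUE, dt = dt,
                  path = if (keep_path) do.call(rbind, path) else NULL))
    }
    x <- x_new
  }
  stop("non-convergence: relinearization did not settle within max_steps")
}

#' Required input deviation for a target state change
#'
#' Inverse (dose-design) problem: find the input deviation \eqn{\Delta u}
#' whose linear steady-state response best matches a desired state deviation
#' \eqn{\Delta x}. From the one-solve prediction,
#' \eqn{\Delta x = -A^{-1} B \Delta u}, so \eqn{B \Delta u = -A \Delta x} is
#' solved in the minimum-norm least-squares sense (pseudoinverse). The
#' residual norm tells callers whether the target is reachable through the
#' available inputs.
#'
#' @param lin a stable [linearize()] result.
#' @param delta_x_target desired state deviation from the anchor.
#' @return list with `du` (input deviation), `residual` (Euclidean norm of
#'   \eqn{B \Delta u + A \Delta x}), and `predicted_dx` (the linear response
#'   actually achieved by `du`).
#' @export
required_input_deviation <- function(lin, delta_x_target) {
  stopifnot(inherits(lin, "linear_model"))
  if (length(delta_x_target) != nrow(lin$A)) stop("target dimension mismatch")
  if (ncol(lin$B) == 0L || all(lin$B == 0)) stop("no actuation: input matrix is zero")
  rhs <- drop(-lin$A %*% delta_x_target)
  du <- drop(pracma::pinv(lin$B) %*% rhs)
  residual <- sqrt(sum((drop(lin$B %*% du) - rhs)^2))
  predicted_dx <- drop(solve(lin$A, -lin$B %*% du))
  list(du = stats::setNames(du, colnames(lin$B)), residual = residual,
       predicted_dx = predicted_dx)
}
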