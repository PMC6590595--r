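#' Construct a plain linear time-invariant system
#'
#' A lightweight model \eqn{dx/dt = A x + B u} sharing the same evaluation
#' interface as [reaction_network()]. Useful as a reference object in
#' stability diagnostics (e.g. a pure-rotation system, which cannot be
#' expressed as a mass-action network because its consumption terms are not
#' first order in the consumed species).
#'
#' @param A square state matrix (1/time).
#' @param B input matrix; defaults to a zero-column matrix (autonomous).
#' @return object of class `linear_system`.
#' @export
linear_system <- function(A, B = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  n <- nrow(A)
  if (is.null(B)) B <- matrix(0, n, 0)
  B <- as.matrix(B)
  if (nrow(B) != n) stop("B must have as many rows as A")
  structure(list(A = A, B = B, n_species = n, n_inputs = ncol(B),
                 species = paste0("x", seq_len(n))),
            class = "linear_system")
}

#' @export
evaluate_rhs.linear_system <- function(model, x, u) {
  if (length(x) != model$n_species) stop("state dimension mismatch")
  if (length(u) != model$n_inputs) stop("input dimension mismatch")
  f <- drop(model$A %*% x)
  if (model$n_inputs) f <- f + drop(model$B %*% u)
  f
}

#' @export
state_jacobian.linear_system <- function(model, x) model$A

#' @export
input_jacobian.linear_system <- function(model) model$B

#' @export
print.linear_system <- function(x, ...) {
  cat("linear_system:", x$n_species, "states,", x$n_inputs, "inputs\n")
  invisible(x)
}
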