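#' Build a mass-action reaction network model
#'
#' Constructs a bilinear ODE model \eqn{dx/dt = f(x, p, u)} from an explicit
#' reaction list with mass-action kinetics. Reactions are at most bimolecular
#' and each species enters the reactant side with stoichiometry at most one,
#' so every consumption term is first order in the consumed species. Exogenous
#' inputs are zero-order inflows: input \eqn{u_j} adds directly to the
#' derivative of its target species. Under this grammar the input Jacobian
#' \eqn{B} is a constant 0/1 incidence matrix and the state Jacobian
#' \eqn{A(x)} never depends on \eqn{u}, so a Taylor linearization discards no
#' input nonlinearities.
#'
#' @param species character vector of species identifiers (state ordering).
#' @param reactions list of reactions; each reaction is a list with elements
#'   `reactants` (named numeric vector of stoichiometries, possibly empty),
#'   `products` (named numeric vector, possibly empty) and `rate_param`
#'   (name of the rate constant in `parameters`).
#' @param parameters named numeric vector of strictly positive rate constants
#'   (units 1/time for unimolecular, 1/(conc time) for bimolecular steps).
#' @param inputs named character vector mapping input names to target species;
#'   its order fixes the input-vector layout. May be empty.
#' @param readouts character vector of species names forming the output
#'   vector `y` (a selection map); order is preserved.
#' @param rate_modifier optional function `(u) -> numeric` returning one
#'   multiplicative factor per reaction. This extension hook deliberately
#'   breaks the input-linearity guarantees and is detected by
#'   [check_linearity_conditions()]; the default `NULL` keeps pure
#'   mass-action kinetics.
#'
#' @return An object of class `reaction_network` with precomputed
#'   stoichiometry and incidence matrices.
#' @seealso [evaluate_rhs()], [state_jacobian()], [decompose_structural_form()]
#' @export
#' @examples
#' net <- reaction_network(
#'   species = c("A", "B", "C"),
#'   reactions = list(
#'     list(reactants = c(A = 1, B = 1), products = c(C = 1), rate_param = "k_bind"),
#'     list(reactants = c(A = 1), products = numeric(), rate_param = "k_degA"),
#'     list(reactants = c(B = 1), products = numeric(), rate_param = "k_degB"),
#'     list(reactants = c(C = 1), products = numeric(), rate_param = "k_degC")
#'   ),
#'   parameters = c(k_bind = 1, k_degA = 1, k_degB = 1, k_degC = 1),
#'   inputs = c(uA = "A", uB = "B"),
#'   readouts = "C"
#' )
#' evaluate_rhs(net, x = c(1, 1, 1), u = c(2, 2))
reaction_network <- function(species, reactions, parameters, inputs = character(),
                             readouts = character(), rate_modifier = NULL) {
  species <- as.character(species)
  n <- length(species)
  if (n < 1L) stop("network needs at least one species")
  if (anyDuplicated(species)) stop("duplicated species identifiers")
  if (length(reactions) < 1L) stop("network needs at least one reaction")
  if (is.null(names(parameters)) || any(!nzchar(names(parameters))))
    stop("parameters must be a named vector")
  if (any(!is.finite(parameters)) || any(parameters <= 0))
    stop("model validation: all rate parameters must be strictly positive and finite")

  nr <- length(reactions)
  N <- matrix(0, n, nr, dimnames = list(species, NULL))
  # reactant species indices per reaction; sentinel n + 1 points at a padded 1
  r1 <- integer(nr); r2 <- integer(nr)
  kval <- numeric(nr); kname <- character(nr)
  for (j in seq_len(nr)) {
    rx <- reactions[[j]]
    if (is.null(rx$rate_param) || !rx$rate_param %in% names(parameters))
      stop("reaction ", j, ": unknown rate parameter '", rx$rate_param, "'")
    rs <- rx$reactants; ps <- rx$products
    if (length(rs) && is.null(names(rs))) stop("reaction ", j, ": reactants must be named")
    if (length(ps) && is.null(names(ps))) stop("reaction ", j, ": products must be named")
    bad <- setdiff(c(names(rs), names(ps)), species)
    if (length(bad)) stop("reaction ", j, ": unknown species '", bad[1], "'")
    if (length(rs) && any(rs != round(rs) | rs < 1)) stop("reaction ", j, ": reactant stoichiometries must be positive integers")
    if (sum(rs) > 2) stop("reaction ", j, ": total reactant order exceeds 2 (at most bimolecular)")
    if (length(rs) && any(rs > 1)) stop("reaction ", j, ": reactant stoichiometry above 1 for one species is not allowed")
    ridx <- match(names(rs), species)
    r1[j] <- if (length(ridx) >= 1) ridx[1] else n + 1L
    r2[j] <- if (length(ridx) >= 2) ridx[2] else n + 1L
    for (s in names(rs)) N[s, j] <- N[s, j] - rs[[s]]
    for (s in names(ps)) N[s, j] <- N[s, j] + ps[[s]]
    kname[j] <- rx$rate_param
    kval[j] <- parameters[[rx$rate_param]]
  }

  m <- length(inputs)
  B <- matrix(0, n, m, dimnames = list(species, names(inputs)))
  if (m) {
    tgt <- match(inputs, species)
    if (anyNA(tgt)) stop("input target species not found: ", inputs[which(is.na(tgt))[1]])
    B[cbind(tgt, seq_len(m))] <- 1
  }

  readouts <- as.character(readouts)
  ridx_out <- match(readouts, species)
  if (anyNA(ridx_out)) stop("unknown readout species: ", readouts[which(is.na(ridx_out))[1]])
  if (anyDuplicated(ridx_out)) stop("readout indices must be distinct")

  if (!is.null(rate_modifier) && !is.function(rate_modifier))
    stop("rate_modifier must be a function of u or NULL")

  structure(list(
    species = species, reactions = reactions, parameters = parameters,
    inputs = inputs, readouts = readouts, readout_idx = ridx_out,
    n_species = n, n_inputs = m, n_reactions = nr,
    stoich = N, B = B, r1 = r1, r2 = r2, k = kval, k_names = kname,
    rate_modifier = rate_modifier
  ), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", x$n_species, "species,", x$n_reactions, "reactions,",
      x$n_inputs, "inputs,", length(x$readouts), "readouts\n")
  invisible(x)
}

reaction_rates <- function(network, x, u = NULL) {
  xe <- c(x, 1)
  rates <- network$k * xe[network$r1] * xe[network$r2]
  if (!is.null(network$rate_modifier)) {
    if (is.null(u)) stop("rate-modified network requires u to evaluate rates")
    rates <- rates * network$rate_modifier(u)
  }
  rates
}

check_x <- function(network, x) {
  if (length(x) != network$n_species)
    stop("state vector has length ", length(x), ", expected ", network$n_species)
  if (any(!is.finite(x))) stop("non-finite entries in state vector")
  invisible(TRUE)
}

check_u <- function(network, u) {
  if (length(u) != network$n_inputs)
    stop("input vector has length ", length(u), ", expected ", network$n_inputs)
  if (any(!is.finite(u))) stop("non-finite entries in input vector")
  invisible(TRUE)
}

#' Evaluate the ODE right-hand side
#'
#' Assembles \eqn{f(x, p, u)} from the network's mass-action terms plus
#' zero-order input inflows.
#'
#' @param model a model object ([reaction_network()] or [linear_system()]).
#' @param x state vector (concentrations, componentwise nonnegative on the
#'   model's domain).
#' @param u input vector (inflow rates).
#' @return numeric vector of state derivatives, one per species.
#' @export
evaluate_rhs <- function(model, x, u) UseMethod("evaluate_rhs")

#' @export
evaluate_rhs.reaction_network <- function(model, x, u) {
  check_x(model, x); check_u(model, u)
  f <- drop(model$stoich %*% reaction_rates(model, x, u))
  if (model$n_inputs) f <- f + drop(model$B %*% u)
  unname(f)
}

#' State Jacobian of the right-hand side
#'
#' Analytic Jacobian \eqn{\partial f / \partial x} assembled from reaction
#' stoichiometry. For pure mass-action networks it does not depend on the
#' input vector, which is why the Taylor linearization's input block is exact.
#'
#' @inheritParams evaluate_rhs
#' @return an `n x n` numeric matrix.
#' @export
state_jacobian <- function(model, x) UseMethod("state_jacobian")

#' @export
state_jacobian.reaction_network <- function(model, x) {
  check_x(model, x)
  n <- model$n_species; nr <- model$n_reactions
  xe <- c(x, 1)
  # d(rate_j)/dx: k for a lone reactant, k*x_other for bimolecular pairs
  R <- matrix(0, nr, n)
  j1 <- which(model$r1 <= n)
  R[cbind(j1, model$r1[j1])] <- model$k[j1] * xe[model$r2[j1]]
  j2 <- which(model$r2 <= n)
  R[cbind(j2, model$r2[j2])] <- R[cbind(j2, model$r2[j2])] + model$k[j2] * xe[model$r1[j2]]
  A <- model$stoich %*% R
  dimnames(A) <- list(model$species, model$species)
  A
}

#' Input Jacobian of the right-hand side
#'
#' The constant 0/1 incidence matrix \eqn{B = \partial f / \partial u} mapping
#' inputs to species inflows. It depends on neither the state nor the input.
#'
#' @inheritParams evaluate_rhs
#' @return an `n x m` numeric matrix.
#' @export
input_jacobian <- function(model) UseMethod("input_jacobian")

#' @export
input_jacobian.reaction_network <- function(model) model$B

#' Evaluate the model outputs
#'
#' The output map \eqn{y = g(x)} is a pure selection: the subvector of the
#' state at the readout indices, in readout order.
#'
#' @inheritParams evaluate_rhs
#' @return numeric vector named by readout species.
#' @export
evaluate_outputs <- function(model, x) UseMethod("evaluate_outputs")

#' @export
evaluate_outputs.reaction_network <- function(model, x) {
  check_x(model, x)
  if (!length(model$readout_idx)) stop("configuration error: no readouts defined")
  stats::setNames(x[model$readout_idx], model$readouts)
}

#' Structural first-order-filter decomposition of one state equation
#'
#' Every state equation of a mass-action network with first-order self-loss
#' can be written as \eqn{\dot x_k = -x_k h_1(x_{-k}, p) + h_2(x_{-k}, p) + u_k}
#' with \eqn{h_1 > c_k > 0} and \eqn{h_2 \ge 0} for nonnegative states,
#' parameters and inputs: each state is a stable first-order filter driven by
#' the rest of the network. This function collects those aggregates for state
#' `k` at a given point and verifies the lower bound on \eqn{h_1}, which
#' requires at least one first-order degradation reaction consuming the
#' species regardless of the rest of the state.
#'
#' @inheritParams evaluate_rhs
#' @param k species index (or name) to decompose.
#' @return list with class `structural_decomposition`: `k`, `h1` (aggregate
#'   first-order loss, 1/time), `h2` (aggregate production, conc/time),
#'   `u_k` (input inflow, conc/time) and `rhs` (the reconstructed
#'   \eqn{\dot x_k}).
#' @export
decompose_structural_form <- function(model, k, x, u) {
  stopifnot(inherits(model, "reaction_network"))
  if (!is.null(model$rate_modifier))
    stop("structural-form decomposition is defined for pure mass-action kinetics only")
  if (is.character(k)) k <- match(k, model$species)
  if (is.na(k) || k < 1 || k > model$n_species) stop("invalid species index k")
  check_x(model, x); check_u(model, u)
  n <- model$n_species
  xe <- c(x, 1)

  # static c_k bound: a first-order reaction consuming k whose rate depends
  # on x_k alone guarantees h1 >= k_rate > 0 everywhere on the domain
  self_loss <- any(model$r1 == k & model$r2 == n + 1L & model$stoich[k, ] < 0)
  if (!self_loss)
    stop("structural-form violation: species '", model$species[k],
         "' has no first-order self-loss reaction (h1 lower bound fails)")

  h1 <- 0; h2 <- 0
  for (j in seq_len(model$n_reactions)) {
    nu <- model$stoich[k, j]
    if (nu == 0) next
    is_reactant <- (model$r1[j] == k || model$r2[j] == k)
    if (is_reactant) {
      other <- if (model$r1[j] == k) model$r2[j] else model$r1[j]
      # rate = k_j * x_k * x_other; the x_k factor is pulled out into h1
      h1 <- h1 - nu * model$k[j] * xe[other]
    } else {
      # k appears only as a product: nu > 0, plain production term
      h2 <- h2 + nu * model$k[j] * xe[model$r1[j]] * xe[model$r2[j]]
    }
  }
  if (h1 <= 0)
    stop("structural-form violation: aggregate loss h1 is not positive for species '",
         model$species[k], "' (autocatalytic production dominates)")
  u_k <- if (model$n_inputs) sum(model$B[k, ] * u) else 0
  h1 <- unname(h1); h2 <- unname(h2); u_k <- unname(u_k)
  structure(list(k = k, species = model$species[k], h1 = h1, h2 = h2, u_k = u_k,
                 rhs = unname(-x[k] * h1 + h2 + u_k)),
            class = "structural_decomposition")
}

#' Check the input-linearity conditions of the model
#'
#' Two conditions make the Taylor linearization exact in the input directions:
#' (i) the input Jacobian is constant, and (ii) the state Jacobian does not
#' depend on the input. Both hold for any pure mass-action network built by
#' [reaction_network()]; the check probes them numerically at random points so
#' that a `rate_modifier` extension injecting input-dependent kinetics is
#' detected.
#'
#' @inheritParams evaluate_rhs
#' @param n_probes number of random probe points (at least 3).
#' @param seed RNG seed for the probe draws.
#' @return list of logical flags `input_jacobian_constant` and
#'   `state_jacobian_u_free`.
#' @export
check_linearity_conditions <- function(model, n_probes = 5, seed = 1L) {
  stopifnot(inherits(model, "reaction_network"), n_probes >= 3)
  n <- model$n_species; m <- model$n_inputs
  if (m == 0L) return(list(input_jacobian_constant = TRUE, state_jacobian_u_free = TRUE))
  B <- input_jacobian(model)
  ok_B <- TRUE; ok_A <- TRUE
  with_preserved_seed(seed, {
    for (i in seq_len(n_probes)) {
      x <- stats::runif(n, 0, 2)
      u1 <- stats::runif(m, 0, 2); u2 <- stats::runif(m, 0, 2)
      df <- evaluate_rhs(model, x, u1) - evaluate_rhs(model, x, u2)
      pred <- drop(B %*% (u1 - u2))
      scale <- max(1, max(abs(df)))
      if (max(abs(df - pred)) > 1e-10 * scale) ok_B <- FALSE
      # state Jacobian probed by finite response differences at two inputs
      dx <- stats::runif(n, -1e-4, 1e-4)
      g1 <- (evaluate_rhs(model, x + dx, u1) - evaluate_rhs(model, x, u1))
      g2 <- (evaluate_rhs(model, x + dx, u2) - evaluate_rhs(model, x, u2))
      if (max(abs(g1 - g2)) > 1e-10 * max(1, max(abs(g1)))) ok_A <- FALSE
    }
  })
  list(input_jacobian_constant = ok_B, state_jacobian_u_free = ok_A)
}

# Run code with a fixed seed, restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
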