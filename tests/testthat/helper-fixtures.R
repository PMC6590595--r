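# Shared fixtures and independent oracles used across the suite.

# Closed-form steady state of the bind2 fixture under a symmetric input
# u = (v, v): A = B = s solves s^2 + s - v = 0, C = s^2.
bind2_ss_exact <- function(v) {
  s <- (-1 + sqrt(1 + 4 * v)) / 2
  c(A = s, B = s, C = s^2)
}

# Central finite-difference state Jacobian: the independent oracle against
# the analytic assembly.
fd_state_jacobian <- function(model, x, u, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- h * max(1, abs(x[i]))
    J[, i] <- (evaluate_rhs(model, x + e, u) - evaluate_rhs(model, x - e, u)) /
      (2 * e[i])
  }
  J
}

fd_input_jacobian <- function(model, x, u, h = 1e-6) {
  m <- length(u)
  n <- model$n_species
  J <- matrix(0, n, m)
  for (i in seq_len(m)) {
    e <- numeric(m); e[i] <- h * max(1, abs(u[i]))
    J[, i] <- (evaluate_rhs(model, x, u + e) - evaluate_rhs(model, x, u - e)) /
      (2 * e[i])
  }
  J
}

# Small random mass-action network: a thinned cascade with every species
# degrading first order, suitable for property sweeps.
random_small_network <- function(seed, n_ligands = 2, n_receptors = 2) {
  generate_wnt_like_network(generator_config(
    n_ligands = n_ligands, n_receptors = n_receptors, n_coreceptors = 1,
    n_readouts = 4, depth = 3, density = 0.8, seed = seed))
}

# Autocatalytic toy with a positive eigenvalue at small states:
# A -> 2A at rate 2 against first-order decay at rate 1 (net growth).
unstable_fixture <- function() {
  reaction_network(
    species = "A",
    reactions = list(
      list(reactants = c(A = 1), products = c(A = 2), rate_param = "k_auto"),
      list(reactants = c(A = 1), products = numeric(), rate_param = "k_deg")
    ),
    parameters = c(k_auto = 2, k_deg = 1),
    inputs = c(u = "A"), readouts = "A")
}
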