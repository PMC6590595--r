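test_that("mass-action RHS reproduces hand-evaluated fixture values", {
  bind2 <- make_toy_model("bind2")
  expect_equal(evaluate_rhs(bind2, c(1, 1, 1), c(2, 2)), c(0, 0, 0))
  expect_equal(evaluate_rhs(bind2, c(2, 1, 0), c(2, 2)), c(-2, -1, 2))

  decay1 <- make_toy_model("decay1")
  expect_equal(evaluate_rhs(decay1, 2, 4), 0)

  expect_error(evaluate_rhs(bind2, c(1, 1), c(2, 2)), "length")
  expect_error(evaluate_rhs(bind2, c(1, 1, 1), 2), "length")
})

test_that("network construction rejects invalid models", {
  expect_error(reaction_network(
    species = "A",
    reactions = list(list(reactants = c(A = 1), products = numeric(),
                          rate_param = "k")),
    parameters = c(k = -1)), "positive")
  expect_error(reaction_network(
    species = c("A", "B"),
    reactions = list(list(reactants = c(A = 1, B = 1, A2 = 1),
                          products = numeric(), rate_param = "k")),
    parameters = c(k = 1)), "unknown species")
  # trimolecular and stoichiometry-2 reactant sides are outside the grammar
  expect_error(reaction_network(
    species = c("A", "B", "C"),
    reactions = list(list(reactants = c(A = 1, B = 1, C = 1),
                          products = numeric(), rate_param = "k")),
    parameters = c(k = 1)), "bimolecular")
  expect_error(reaction_network(
    species = "A",
    reactions = list(list(reactants = c(A = 2), products = numeric(),
                          rate_param = "k")),
    parameters = c(k = 1)), "stoichiometry")
})

test_that("analytic Jacobians match fixture values and are input-free", {
  bind2 <- make_toy_model("bind2")
  expect_equal(unname(state_jacobian(bind2, c(1, 1, 1))),
               matrix(c(-2, -1, 0, -1, -2, 0, 1, 1, -1), 3, byrow = TRUE))
  expect_equal(unname(state_jacobian(make_toy_model("decay1"), 7)),
               matrix(-2, 1, 1))
  expect_equal(unname(input_jacobian(bind2)),
               matrix(c(1, 0, 0, 1, 0, 0), 3, byrow = TRUE))
  # constancy: same matrix whatever the state
  expect_identical(input_jacobian(bind2), input_jacobian(bind2))
})

test_that("analytic Jacobians agree with central finite differences on random draws", {
  set.seed(42)
  for (rep in 1:12) {
    net <- random_small_network(seed = rep)
    x <- runif(net$n_species, 0.05, 3)
    u <- runif(net$n_inputs, 0.05, 3)
    A <- state_jacobian(net, x)
    A_fd <- fd_state_jacobian(net, x, u)
    expect_lt(max(abs(A - A_fd)) / max(1, max(abs(A))), 1e-5)
    B_fd <- fd_input_jacobian(net, x, u)
    expect_lt(max(abs(input_jacobian(net) - B_fd)), 1e-7)
  }
})

test_that("structural decomposition collects first-order loss and production", {
  bind2 <- make_toy_model("bind2")
  dA <- decompose_structural_form(bind2, "A", c(1, 1, 1), c(2, 2))
  expect_equal(dA$h1, 2)   # x_B + degradation rate
  expect_equal(dA$h2, 0)
  expect_equal(dA$u_k, 2)
  dC <- decompose_structural_form(bind2, "C", c(1, 1, 1), c(2, 2))
  expect_equal(dC$h1, 1)
  expect_equal(dC$h2, 1)   # x_A * x_B
  expect_equal(dC$u_k, 0)
  d1 <- decompose_structural_form(make_toy_model("decay1"), 1, 3, 4)
  expect_equal(d1$h1, 2); expect_equal(d1$h2, 0); expect_equal(d1$u_k, 4)
})

test_that("structural reconstruction matches the RHS for random states", {
  set.seed(7)
  for (rep in 1:5) {
    net <- random_small_network(seed = 20 + rep)
    x <- runif(net$n_species, 0, 2)
    u <- runif(net$n_inputs, 0, 2)
    f <- evaluate_rhs(net, x, u)
    for (k in seq_len(net$n_species)) {
      d <- decompose_structural_form(net, k, x, u)
      expect_gt(d$h1, 0)
      expect_gte(d$h2, 0)
      expect_lt(abs(d$rhs - f[k]), 1e-12 * max(1, abs(f[k])))
    }
  }
})

test_that("species without first-order self-loss violate the structural form", {
  net <- reaction_network(
    species = c("A", "B"),
    reactions = list(
      list(reactants = c(A = 1, B = 1), products = numeric(), rate_param = "k1"),
      list(reactants = c(B = 1), products = numeric(), rate_param = "k2")
    ),
    parameters = c(k1 = 1, k2 = 1), inputs = c(u = "A"), readouts = "A")
  # A is only consumed jointly with B: no lower bound on its loss rate
  expect_error(decompose_structural_form(net, "A", c(1, 1), 1),
               "structural-form violation")
  expect_silent(decompose_structural_form(net, "B", c(1, 1), 1))
})

test_that("the RHS is exactly linear in the input space", {
  set.seed(99)
  net <- random_small_network(seed = 31)
  B <- input_jacobian(net)
  for (rep in 1:10) {
    x <- runif(net$n_species, 0, 2)
    u1 <- runif(net$n_inputs, 0, 3)
    u2 <- runif(net$n_inputs, 0, 3)
    lhs <- evaluate_rhs(net, x, u1) - evaluate_rhs(net, x, u2)
    expect_equal(lhs, unname(drop(B %*% (u1 - u2))), tolerance = 1e-14)
  }
  flags <- check_linearity_conditions(net)
  expect_true(flags$input_jacobian_constant)
  expect_true(flags$state_jacobian_u_free)
})

test_that("input-dependent kinetics injected via the hook are detected", {
  bad <- reaction_network(
    species = "A",
    reactions = list(list(reactants = c(A = 1), products = numeric(),
                          rate_param = "k")),
    parameters = c(k = 1), inputs = c(u = "A"), readouts = "A",
    rate_modifier = function(u) 1 + u[1])
  flags <- check_linearity_conditions(bad)
  expect_false(flags$input_jacobian_constant)
  expect_false(flags$state_jacobian_u_free)
})

test_that("outputs select readout states in order", {
  bind2 <- make_toy_model("bind2")
  expect_equal(unname(evaluate_outputs(bind2, c(1, 1, 1))), 1)
  net <- reaction_network(
    species = c("A", "B", "C"),
    reactions = list(list(reactants = c(A = 1), products = numeric(),
                          rate_param = "k")),
    parameters = c(k = 1), inputs = c(u = "A"), readouts = c("C", "A"))
  expect_equal(evaluate_outputs(net, c(2, 1, 3)), c(C = 3, A = 2))
})
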