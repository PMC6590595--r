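test_that("linearization anchors the hand-derived A and B matrices", {
  bind2 <- make_toy_model("bind2")
  ss <- simulate_to_steady_state(bind2, c(2, 2))
  lin <- linearize(bind2, ss)
  expect_equal(unname(lin$A),
               matrix(c(-2, -1, 0, -1, -2, 0, 1, 1, -1), 3, byrow = TRUE),
               tolerance = 1e-8)
  expect_equal(unname(lin$B), matrix(c(1, 0, 0, 1, 0, 0), 3, byrow = TRUE))
  expect_equal(sort(Re(lin$eigenvalues)), c(-3, -1, -1), tolerance = 1e-8)
  expect_true(lin$stable)
  expect_true(lin$hyperbolic)

  d1 <- make_toy_model("decay1")
  lin1 <- linearize(d1, simulate_to_steady_state(d1, 4))
  expect_equal(unname(lin1$A), matrix(-2, 1, 1))
  expect_equal(unname(lin1$B), matrix(1, 1, 1))

  fake <- structure(list(x_ss = c(5, 5, 5), u_bf = c(2, 2), residual_norm = 1,
                         t_converged = 0, method = "none", tol_ss = 1e-9),
                    class = "steady_state")
  expect_error(linearize(bind2, fake), "precondition")
})

test_that("the linearization of a linear model is exact everywhere", {
  aff <- make_toy_model("affine_n", n = 7)
  ss <- simulate_to_steady_state(aff, c(1, 2))
  lin <- linearize(aff, ss)
  set.seed(3)
  for (i in 1:10) {
    x <- runif(7, 0, 4); u <- runif(2, 0, 4)
    f_lin <- drop(lin$A %*% (x - as.numeric(ss$x_ss))) +
      drop(lin$B %*% (u - ss$u_bf))
    expect_lt(max(abs(f_lin - evaluate_rhs(aff, x, u))), 1e-10)
  }
})

test_that("one-solve steady-state prediction matches fixture oracles", {
  bind2 <- make_toy_model("bind2")
  ss <- simulate_to_steady_state(bind2, c(2, 2))
  lin <- linearize(bind2, ss)
  expect_equal(as.numeric(linear_steady_state(lin, c(2, 2))),
               as.numeric(ss$x_ss), tolerance = 1e-10)
  expect_equal(as.numeric(linear_steady_state(lin, c(2.2, 2.2))),
               c(16 / 15, 16 / 15, 17 / 15), tolerance = 1e-8)

  d1 <- make_toy_model("decay1")
  lin1 <- linearize(d1, simulate_to_steady_state(d1, 4))
  expect_equal(as.numeric(linear_steady_state(lin1, 6)), 3, tolerance = 1e-10)
})

test_that("one-solve prediction equals integrating the deviation dynamics", {
  set.seed(17)
  for (s in 1:6) {
    net <- random_small_network(seed = 400 + s)
    u_bf <- runif(net$n_inputs, 0.2, 2)
    ss <- simulate_to_steady_state(net, u_bf)
    lin <- linearize(net, ss)
    u_new <- u_bf * runif(net$n_inputs, 0.8, 1.2)
    pred <- linear_steady_state(lin, u_new) - as.numeric(ss$x_ss)
    dev_model <- linear_system(lin$A, lin$B)
    dev_ss <- simulate_to_steady_state(dev_model, u_new - u_bf,
                                       x0 = numeric(net$n_species),
                                       rtol = 1e-10, atol = 1e-12)
    # the deviation model's rest point may be negative; compare unclipped
    dev_raw <- reactlin:::newton_refine(dev_model, as.numeric(dev_ss$x_ss),
                                        u_new - u_bf)$x
    expect_lt(max(abs(dev_raw - pred)) / max(1, max(abs(pred))), 1e-7)
  }
})

test_that("clipping is the idempotent componentwise positive part", {
  expect_equal(clip_nonnegative(c(-0.2, 1.0)), c(0, 1.0))
  x <- c(0.5, 0, 2)
  expect_identical(clip_nonnegative(x), x)
  y <- c(-1, 0.3, -1e-9)
  expect_identical(clip_nonnegative(clip_nonnegative(y)), clip_nonnegative(y))
})

test_that("hyperbolicity and stability flags follow the eigenvalues", {
  bind2 <- make_toy_model("bind2")
  ss <- simulate_to_steady_state(bind2, c(2, 2))
  hb <- check_hyperbolic(linearize(bind2, ss))
  expect_true(hb$hyperbolic); expect_true(hb$stable)

  rot <- check_hyperbolic(matrix(c(0, 1, -1, 0), 2, byrow = TRUE))
  expect_false(rot$hyperbolic); expect_false(rot$stable)

  saddle <- check_hyperbolic(diag(c(-1, 2)))
  expect_true(saddle$hyperbolic); expect_false(saddle$stable)
})

test_that("relinearization tracks the nonlinear dynamics ever closer as dt shrinks", {
  bind2 <- make_toy_model("bind2")
  ss <- simulate_to_steady_state(bind2, c(2, 2))
  target <- bind2_ss_exact(2.2)[["C"]]
  res <- iterative_relinearization(bind2, c(2.2, 2.2), ss, dt = 0.01)
  expect_true(res$converged)
  expect_lt(abs(res$x[["C"]] - target), 1e-3)

  # the iterated scheme lands on the nonlinear fixed point for every dt;
  # the dt-dependence shows in how closely the path follows the trajectory
  errs <- sapply(c(0.4, 0.2, 0.1), function(dt) {
    r <- iterative_relinearization(bind2, c(2.2, 2.2), ss, dt = dt,
                                   keep_path = TRUE)
    expect_lt(max(abs(as.numeric(r$x) - unname(bind2_ss_exact(2.2)))), 1e-8)
    K <- nrow(r$path)
    tr <- simulate_trajectory(bind2, c(2.2, 2.2), as.numeric(ss$x_ss),
                              seq(0, K * dt, by = dt),
                              rtol = 1e-11, atol = 1e-13)
    max(abs(r$path - as.matrix(tr[-1, -1])))
  })
  expect_true(all(diff(errs) < 0))

  # constant Jacobian: a single unbounded step lands on the one-solve answer
  aff <- make_toy_model("affine_n", n = 5)
  ssa <- simulate_to_steady_state(aff, c(1, 1))
  lina <- linearize(aff, ssa)
  one <- iterative_relinearization(aff, c(1.5, 0.8), ssa, dt = Inf)
  expect_lte(one$n_steps, 2L)
  expect_equal(as.numeric(one$x),
               as.numeric(linear_steady_state(lina, c(1.5, 0.8))),
               tolerance = 1e-9)
})

test_that("required input deviation solves the inverse dose problem", {
  bind2 <- make_toy_model("bind2")
  ss <- simulate_to_steady_state(bind2, c(2, 2))
  lin <- linearize(bind2, ss)

  z <- required_input_deviation(lin, c(0, 0, 0))
  expect_equal(as.numeric(z$du), c(0, 0))

  r <- required_input_deviation(lin, c(0.1, 0.1, 0.2))
  expect_equal(as.numeric(r$du), c(0.3, 0.3), tolerance = 1e-10)
  expect_lt(r$residual, 1e-10)
  # round trip: the achieved linear response reproduces the target
  back <- linear_steady_state(lin, ss$u_bf + r$du) - as.numeric(ss$x_ss)
  expect_equal(as.numeric(back), c(0.1, 0.1, 0.2), tolerance = 1e-8)

  no_act <- structure(list(A = lin$A, B = matrix(0, 3, 2), x_ss = lin$x_ss,
                           u_bf = lin$u_bf, eigenvalues = lin$eigenvalues,
                           stable = TRUE, hyperbolic = TRUE),
                      class = "linear_model")
  expect_error(required_input_deviation(no_act, c(0.1, 0, 0)), "no actuation")
})

test_that("the steady-state error scales quadratically in the perturbation", {
  bind2 <- make_toy_model("bind2")
  ss <- simulate_to_steady_state(bind2, c(2, 2))
  lin <- linearize(bind2, ss)
  du <- c(0.01, 0.02, 0.04)
  errs <- sapply(du, function(d) {
    nl <- bind2_ss_exact(2 + d)
    li <- linear_steady_state(lin, c(2 + d, 2 + d))
    sqrt(sum((unname(nl) - as.numeric(li))^2))
  })
  slopes <- diff(log(errs)) / diff(log(du))
  expect_true(all(slopes > 1.7 & slopes < 2.3))
  # first-order correctness: e/||du|| -> 0
  expect_lt(errs[1] / du[1], errs[3] / du[3])
})
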