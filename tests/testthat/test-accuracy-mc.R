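test_that("multiplicative perturbation obeys the bounded-noise formula", {
  expect_equal(perturb_inputs(c(3, 5), 0, c(0.2, 0.9)), c(3, 5))
  expect_equal(perturb_inputs(c(2, 2), 0.5, c(0, 1)), c(3, 1))
  expect_equal(perturb_inputs(rep(4, 6), 0.3, rep(0.5, 6)), rep(4, 6))
  expect_error(perturb_inputs(c(1, 1), 0.1, c(-0.1, 0.5)), "contract")
  expect_error(perturb_inputs(c(1, 1), 1.2, c(0.5, 0.5)), "contract")
  expect_error(perturb_inputs(c(-1, 1), 0.1, c(0.5, 0.5)), "contract")

  set.seed(8)
  for (r in c(0.10, 0.25, 0.50)) {
    d <- matrix(runif(2e4), ncol = 4)
    for (i in seq_len(nrow(d))) {
      u <- perturb_inputs(rep(1, 4), r, d[i, ])
      expect_true(all(u >= 1 - r - 1e-12 & u <= 1 + r + 1e-12))
    }
  }
})

test_that("error metrics reproduce forced arithmetic and guard denominators", {
  m0 <- compute_metrics(c(2, 1), c(2, 1), c(1, 1))
  expect_equal(m0$mse, 0); expect_equal(m0$mre_pct, 0)

  m <- compute_metrics(c(3, 1), c(2, 1), c(1, 1))
  expect_equal(m$mse, 0.5)
  expect_equal(m$mre_pct, 25)
  expect_equal(m$std_ratio_pct, 100)
  expect_equal(m$n_excluded, 0L)

  # clipped-to-zero prediction against a nonlinear state that decayed to ~0:
  # the tiny denominator is excluded instead of blowing up the mean
  mg <- compute_metrics(c(0, 1.5), c(1e-15, 1), c(0.5, 1))
  expect_equal(mg$n_excluded, 1L)
  expect_equal(mg$mre_pct, 50)
  expect_true(is.finite(mg$mre_pct))
  expect_error(compute_metrics(c(0, 1), c(0, 0), c(1, 1)), "undefined metric")
})

test_that("readout-scope metrics equal all-state metrics restricted to readouts", {
  set.seed(31)
  xl <- runif(10, 0.5, 2); xn <- runif(10, 0.5, 2); x0 <- runif(10, 0.5, 2)
  idx <- c(2L, 5L, 9L)
  direct <- compute_metrics(xl, xn, x0, scope_indices = idx)
  restricted <- compute_metrics(xl[idx], xn[idx], x0[idx])
  expect_equal(direct$mse, restricted$mse)
  expect_equal(direct$mre_pct, restricted$mre_pct)
  expect_equal(direct$std_ratio_pct, restricted$std_ratio_pct)
})

test_that("a purely linear model yields zero Monte Carlo error at all noise levels", {
  aff <- make_toy_model("affine_n", n = 6)
  inputs <- sample_base_inputs(4, 2, seed = 6)
  rep_aff <- run_workflow(aff, inputs, seed = 2)
  expect_equal(rep_aff$n_failed, 0L)
  expect_true(all(rep_aff$metrics$mse < 1e-14))
  expect_true(all(rep_aff$metrics$mre_pct < 1e-5))
  tr <- fit_error_trend(rep_aff)
  expect_true(tr$exact_linear)
})

test_that("the trend fitter recovers known polynomial orders", {
  fake <- function(expo) {
    structure(list(metrics = data.frame(
      workflow = 1, r_noise = c(0.1, 0.25, 0.5), scope = "all_states",
      mse = 1, mre_pct = 3 * c(0.1, 0.25, 0.5)^expo,
      std_ratio_pct = 1, n_excluded = 0, n_samples = 1)),
      class = "mc_report")
  }
  expect_equal(fit_error_trend(fake(2))$slope, 2, tolerance = 1e-10)
  expect_equal(fit_error_trend(fake(1))$slope, 1, tolerance = 1e-10)
  expect_true(fit_error_trend(fake(2))$monotone)
})

test_that("errors grow with noise range on a nonlinear desk model", {
  net <- generate_wnt_like_network(generator_preset("desk", seed = 23))
  inputs <- sample_base_inputs(8, net$n_inputs, seed = 14)
  rep <- run_workflow(net, inputs, seed = 9)
  for (sc in c("all_states", "readouts")) {
    d <- rep$metrics[rep$metrics$scope == sc, ]
    d <- d[order(d$r_noise), ]
    expect_true(all(diff(d$mre_pct) > 0))
    expect_true(all(diff(d$mse) > 0))
    expect_gt(d$mre_pct[3] / d$mre_pct[1], 3)
    # the linear model captures most of the small-perturbation response
    expect_gt(d$std_ratio_pct[1], 0)
    expect_lt(d$std_ratio_pct[1], 100)
  }
})

test_that("experiment-level runs keep per-workflow parameter draws separate", {
  net <- generate_wnt_like_network(generator_config(2, 2, 1, n_readouts = 4,
                                                    depth = 2, density = 0.8,
                                                    seed = 3))
  inputs <- sample_base_inputs(3, net$n_inputs, seed = 4)
  ex <- run_mc_experiment(net, inputs, n_workflows = 2, seed = 40)
  expect_equal(nrow(ex$metrics), 2 * 3 * 2)
  expect_setequal(unique(ex$metrics$workflow), c(1, 2))
  # distinct parameter vectors produce distinct error levels
  m1 <- ex$metrics[ex$metrics$workflow == 1 & ex$metrics$scope == "all_states", "mre_pct"]
  m2 <- ex$metrics[ex$metrics$workflow == 2 & ex$metrics$scope == "all_states", "mre_pct"]
  expect_false(isTRUE(all.equal(m1, m2)))
  n1 <- resample_parameters(net, seed = 41)
  expect_identical(n1$species, net$species)
  expect_false(identical(n1$parameters, net$parameters))
})

test_that("relative readout ratios agree between simulation and linear path", {
  bind2 <- make_toy_model("bind2")
  same <- relative_dataset_ratios(bind2, c(2, 2), list(c(2, 2)))
  expect_equal(as.numeric(same[[1]]), 1, tolerance = 1e-8)

  nl <- relative_dataset_ratios(bind2, c(2, 2), list(c(2.2, 2.2)))
  expect_equal(as.numeric(nl[[1]]), bind2_ss_exact(2.2)[["C"]], tolerance = 1e-6)
  li <- relative_dataset_ratios(bind2, c(2, 2), list(c(2.2, 2.2)),
                                use_linear = TRUE)
  expect_equal(as.numeric(li[[1]]), 17 / 15, tolerance = 1e-6)
  # up-regulation shows as ratio > 1, down-regulation as < 1
  both <- relative_dataset_ratios(bind2, c(2, 2), list(c(2.5, 2.5), c(1.5, 1.5)))
  expect_gt(as.numeric(both[[1]]), 1)
  expect_lt(as.numeric(both[[2]]), 1)
})
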