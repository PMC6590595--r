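#' Apply bounded multiplicative noise to a base input vector
#'
#' Perturbs each component by a factor in \eqn{[1 - r, 1 + r]}:
#' \eqn{u_i = (1 + r - 2 r d) \circ u_{bf}} (Hadamard product), where the
#' direction vector `d` has entries in \eqn{[0, 1]}. `d = 0` gives the upper
#' extreme, `d = 1` the lower, and `d = 1/2` leaves the input unchanged.
#'
#' @param u_bf positive base input vector.
#' @param r_noise noise range as a fraction in `[0, 1)` (e.g. `0.10` for 10%).
#' @param d direction vector, entries in `[0, 1]`, same length as `u_bf`.
#' @return perturbed input vector.
#' @export
perturb_inputs <- function(u_bf, r_noise, d) {
  if (length(d) != length(u_bf)) stop("direction vector length mismatch")
  if (any(d < 0 | d > 1)) stop("contract error: direction entries must lie in [0, 1]")
  if (r_noise < 0 || r_noise >= 1) stop("contract error: r_noise must lie in [0, 1)")
  if (any(u_bf <= 0)) stop("contract error: base inputs must be positive")
  (1 + r_noise - 2 * r_noise * d) * u_bf
}

#' Linearization-error metrics at steady state
#'
#' Compares a (clipped) linear steady-state prediction against the nonlinear
#' steady state over a component scope:
#' * `mse`: mean of squared componentwise errors;
#' * `mre_pct`: mean of \eqn{|x_{lin} - x_{nonlin}| / x_{nonlin}} in percent,
#'   excluding components whose nonlinear value falls below `eps_den` (a
#'   near-zero denominator would dominate the mean without carrying physical
#'   meaning);
#' * `std_ratio_pct`: sample standard deviation of the error vector divided
#'   by that of the response \eqn{x_{diff} = x_{nonlin} - x_{ss0}}, in
#'   percent — how much of the response's spread the linearization misses.
#'
#' @param x_lin_ss linear steady-state prediction (already clipped to
#'   nonnegative values).
#' @param x_nonlin_ss nonlinear steady state after the perturbation.
#' @param x_ss0 the linearization anchor state.
#' @param scope_indices indices over which to compute the metrics; `NULL`
#'   means all components.
#' @param eps_den_factor relative denominator guard: components with
#'   `x_nonlin_ss < eps_den_factor * max(x_nonlin_ss[scope])` are excluded
#'   from the relative error.
#' @return list of class `error_metrics`: `mse`, `mre_pct`, `std_ratio_pct`,
#'   `n_excluded`, `n_scope`.
#' @export
compute_metrics <- function(x_lin_ss, x_nonlin_ss, x_ss0, scope_indices = NULL,
                            eps_den_factor = 1e-9) {
  stopifnot(length(x_lin_ss) == length(x_nonlin_ss),
            length(x_lin_ss) == length(x_ss0))
  idx <- if (is.null(scope_indices)) seq_along(x_lin_ss) else scope_indices
  xl <- as.numeric(x_lin_ss)[idx]
  xn <- as.numeric(x_nonlin_ss)[idx]
  x0 <- as.numeric(x_ss0)[idx]
  e <- xl - xn
  x_diff <- xn - x0
  eps_den <- eps_den_factor * max(xn, 0)
  ok <- xn >= eps_den & xn > 0
  if (!any(ok)) stop("undefined metric: all components excluded from the relative error")
  sd_diff <- stats::sd(x_diff)
  structure(list(
    mse = mean(e^2),
    mre_pct = 100 * mean(abs(e[ok]) / xn[ok]),
    std_ratio_pct = if (isTRUE(sd_diff > 0)) 100 * stats::sd(e) / sd_diff else NA_real_,
    n_excluded = sum(!ok),
    n_scope = length(idx)
  ), class = "error_metrics")
}

#' Monte Carlo linearization-accuracy workflow
#'
#' For each base input sample: forward-simulate the nonlinear model from the
#' origin to its steady state \eqn{x_{ss0}}, linearize there, then for every
#' noise range perturb the input with [perturb_inputs()] (one direction
#' vector per sample, drawn once and reused across all noise ranges), run the
#' agreement system from \eqn{[0; x_{ss0}]}, clip the linear prediction, and
#' score it with [compute_metrics()] at both the all-states and readouts
#' scopes. Metrics are arithmetically averaged over input samples. Samples
#' whose simulation fails are excluded and counted.
#'
#' @param network a [reaction_network()] with at least one readout.
#' @param base_inputs list of positive base input vectors (e.g. from
#'   [sample_base_inputs()]).
#' @param r_noise_list noise ranges as fractions; default the three standard
#'   levels 10%, 25%, 50%.
#' @param seed RNG seed for the perturbation directions.
#' @param workflow_id identifier recorded in the report rows.
#' @param tol_ss,rtol,atol numerical tolerances passed to the simulators.
#' @param eps_den_factor see [compute_metrics()].
#' @return object of class `mc_report`: `metrics` (data.frame with one row
#'   per noise range and scope), `n_failed`, `meta`.
#' @export
run_workflow <- function(network, base_inputs, r_noise_list = c(0.10, 0.25, 0.50),
                         seed = 1L, workflow_id = 1L, tol_ss = 1e-9,
                         rtol = 1e-8, atol = 1e-10, eps_den_factor = 1e-9) {
  stopifnot(length(base_inputs) >= 1, all(r_noise_list >= 0 & r_noise_list < 1))
  m <- network$n_inputs
  n_s <- length(base_inputs)
  directions <- with_preserved_seed(seed, {
    lapply(seq_len(n_s), function(i) stats::runif(m))
  })
  scopes <- list(all_states = seq_len(network$n_species),
                 readouts = network$readout_idx)
  acc <- list(); n_failed <- 0L
  for (i in seq_len(n_s)) {
    res_i <- tryCatch({
      u_bf <- base_inputs[[i]]
      ss0 <- simulate_to_steady_state(network, u_bf, tol_ss = tol_ss,
                                      rtol = rtol, atol = atol)
      lin <- linearize(network, ss0)
      ag <- build_agreement_system(network, lin)
      out <- list()
      for (r in r_noise_list) {
        u_i <- perturb_inputs(u_bf, r, directions[[i]])
        sim <- simulate_agreement(ag, u_i, tol_ss = tol_ss, rtol = rtol, atol = atol)
        x_lin <- clip_nonnegative(as.numeric(ss0$x_ss) + as.numeric(sim$x_dev_ss))
        for (sc in names(scopes)) {
          mt <- compute_metrics(x_lin, sim$x_nonlin_ss, ss0$x_ss,
                                scope_indices = scopes[[sc]],
                                eps_den_factor = eps_den_factor)
          out[[length(out) + 1L]] <- data.frame(
            r_noise = r, scope = sc, mse = mt$mse, mre_pct = mt$mre_pct,
            std_ratio_pct = mt$std_ratio_pct, n_excluded = mt$n_excluded)
        }
      }
      do.call(rbind, out)
    }, error = function(e) NULL)
    if (is.null(res_i)) n_failed <- n_failed + 1L else acc[[length(acc) + 1L]] <- res_i
  }
  if (!length(acc)) stop("all input samples failed to simulate")
  detail <- do.call(rbind, acc)
  agg <- stats::aggregate(cbind(mse, mre_pct, std_ratio_pct, n_excluded) ~
                            r_noise + scope, data = detail, FUN = mean)
  agg <- agg[order(agg$scope, agg$r_noise), ]
  rownames(agg) <- NULL
  agg <- cbind(workflow = workflow_id, agg,
               n_samples = n_s - n_failed)
  structure(list(metrics = agg, n_failed = n_failed,
                 meta = list(seed = seed, workflow_id = workflow_id,
                             n_samples = n_s, r_noise_list = r_noise_list)),
            class = "mc_report")
}

#' Repeat the accuracy workflow over several random parameter vectors
#'
#' Mirrors the standard experiment layout: the same base-input set is reused
#' across `n_workflows` runs, each with a freshly drawn log-uniform rate
#' vector on the fixed topology and its own perturbation directions.
#'
#' @param network topology template; its rate constants are redrawn per
#'   workflow with [sample_parameters()].
#' @param base_inputs list of base input vectors shared by all workflows.
#' @param n_workflows number of parameter vectors.
#' @param r_noise_list noise ranges.
#' @param seed master seed; workflow `w` uses `seed + w` for parameters and
#'   directions.
#' @param ... passed to [run_workflow()].
#' @return `mc_report` with one row per (workflow, noise range, scope).
#' @export
run_mc_experiment <- function(network, base_inputs, n_workflows = 4L,
                              r_noise_list = c(0.10, 0.25, 0.50), seed = 1L, ...) {
  rows <- list(); failed <- 0L
  for (w in seq_len(n_workflows)) {
    net_w <- resample_parameters(network, seed = seed + w)
    rep_w <- run_workflow(net_w, base_inputs, r_noise_list = r_noise_list,
                          seed = seed + w, workflow_id = w, ...)
    rows[[w]] <- rep_w$metrics
    failed <- failed + rep_w$n_failed
  }
  structure(list(metrics = do.call(rbind, rows), n_failed = failed,
                 meta = list(seed = seed, n_workflows = n_workflows,
                             n_samples = length(base_inputs),
                             r_noise_list = r_noise_list)),
            class = "mc_report")
}

#' Redraw the rate constants of a network
#'
#' Keeps the topology (species, reactions, inputs, readouts) and replaces all
#' rate constants with a fresh log-uniform draw.
#'
#' @param network a [reaction_network()].
#' @param seed RNG seed.
#' @param log10_range exponent range of the log-uniform draw.
#' @return a new [reaction_network()].
#' @export
resample_parameters <- function(network, seed = 1L, log10_range = c(-1, 1)) {
  p <- sample_parameters(length(network$parameters), seed = seed,
                         log10_range = log10_range)
  names(p) <- names(network$parameters)
  reaction_network(species = network$species, reactions = network$reactions,
                   parameters = p, inputs = network$inputs,
                   readouts = network$readouts,
                   rate_modifier = network$rate_modifier)
}

#' @export
print.mc_report <- function(x, ...) {
  cat("mc_report:", nrow(x$metrics), "rows;", x$n_failed, "failed samples\n")
  print(x$metrics, digits = 4)
  invisible(x)
}

#' Fit the error-growth trend over noise ranges
#'
#' Least-squares slope of `log(MRE)` versus `log(r_noise)` for one scope. A
#' slope near 2 reflects the second-order origin of the linearization error
#' (the first discarded Taylor term is quadratic in the state deviation).
#'
#' @param report an `mc_report`.
#' @param scope `"all_states"` or `"readouts"`.
#' @return list with `slope`, `intercept`, `monotone` (is the mean MRE
#'   nondecreasing in the noise range), and `exact_linear` (`TRUE` when MRE
#'   vanishes at all levels, e.g. for a purely linear model, in which case
#'   the slope is undefined).
#' @export
fit_error_trend <- function(report, scope = "all_states") {
  stopifnot(inherits(report, "mc_report"))
  d <- report$metrics[report$metrics$scope == scope, ]
  mre <- stats::aggregate(mre_pct ~ r_noise, data = d, FUN = mean)
  if (nrow(mre) < 3) stop("need at least 3 noise ranges to fit a trend")
  if (all(mre$mre_pct < 1e-9))
    return(list(slope = NA_real_, intercept = NA_real_, monotone = TRUE,
                exact_linear = TRUE))
  fit <- stats::lm(log(mre_pct) ~ log(r_noise), data = mre)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       monotone = !is.unsorted(mre$mre_pct[order(mre$r_noise)]),
       exact_linear = FALSE)
}

#' Readout ratios between input conditions
#'
#' For relative datasets, a data sample is the ratio of the readout vector
#' under a variant input to the readout vector under the base input. The
#' variant steady states are computed either by nonlinear simulation (started
#' from the base steady state) or by the clipped one-solve linear prediction.
#'
#' @param network a [reaction_network()] with readouts.
#' @param u_base base input vector (its steady-state outputs must be
#'   strictly positive).
#' @param u_variants list of variant input vectors.
#' @param use_linear use the linearized prediction instead of nonlinear
#'   simulation.
#' @param ... tolerances passed to the simulator.
#' @return list of named ratio vectors, one per variant.
#' @export
relative_dataset_ratios <- function(network, u_base, u_variants,
                                    use_linear = FALSE, ...) {
  ss0 <- simulate_to_steady_state(network, u_base, ...)
  y_base <- evaluate_outputs(network, as.numeric(ss0$x_ss))
  if (any(y_base <= 0))
    stop("ratio undefined: base steady state has a zero readout component")
  lin <- if (use_linear) linearize(network, ss0) else NULL
  lapply(u_variants, function(uv) {
    x_v <- if (use_linear) {
      linear_steady_state(lin, uv, clip = TRUE)
    } else {
      as.numeric(simulate_to_steady_state(network, uv,
                                          x0 = as.numeric(ss0$x_ss), ...)$x_ss)
    }
    evaluate_outputs(network, as.numeric(x_v)) / y_base
  })
}
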