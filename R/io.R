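## Serialization: model specs as JSON/YAML, linearizations and steady states
## as JSON, Monte Carlo reports as JSON/CSV. Floats are written with 12
## significant digits so that re-serialized files diff cleanly.

model_to_spec <- function(network) {
  list(
    species = as.list(network$species),
    reactions = lapply(network$reactions, function(rx) list(
      reactants = if (length(rx$reactants)) as.list(rx$reactants) else stats::setNames(list(), character()),
      products = if (length(rx$products)) as.list(rx$products) else stats::setNames(list(), character()),
      rate_param = rx$rate_param
    )),
    parameters = as.list(network$parameters),
    inputs = as.list(network$inputs),
    readouts = as.list(network$readouts)
  )
}

spec_to_model <- function(spec) {
  for (field in c("species", "reactions", "parameters"))
    if (is.null(spec[[field]])) stop("parse error: missing field '", field, "'")
  to_named_num <- function(x) {
    if (is.null(x) || !length(x)) return(numeric())
    stats::setNames(as.numeric(unlist(x)), names(x))
  }
  reactions <- lapply(seq_along(spec$reactions), function(j) {
    rx <- spec$reactions[[j]]
    if (is.null(rx$rate_param)) stop("parse error: reaction ", j, " lacks 'rate_param'")
    list(reactants = to_named_num(rx$reactants),
         products = to_named_num(rx$products),
         rate_param = rx$rate_param)
  })
  inputs <- if (length(spec$inputs)) {
    stats::setNames(as.character(unlist(spec$inputs)), names(spec$inputs))
  } else character()
  reaction_network(
    species = as.character(unlist(spec$species)),
    reactions = reactions,
    parameters = to_named_num(spec$parameters),
    inputs = inputs,
    readouts = as.character(unlist(spec$readouts))
  )
}

is_yaml_path <- function(path) grepl("\\.ya?ml$", path, ignore.case = TRUE)

#' Read a reaction-network model specification
#'
#' Parses a JSON or YAML model document (`species`, `reactions`,
#' `parameters`, `inputs`, `readouts`) and validates it through
#' [reaction_network()]. Writing a model back with [write_model()] and
#' re-reading it yields an identical network.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` for
#'   YAML, anything else parsed as JSON).
#' @return a [reaction_network()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- if (is_yaml_path(path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = FALSE)
  spec_to_model(spec)
}

#' Write a reaction-network model specification
#'
#' @param network a [reaction_network()].
#' @param path output path; `.yaml`/`.yml` selects YAML, otherwise JSON.
#' @return `path`, invisibly.
#' @export
write_model <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  spec <- model_to_spec(network)
  if (is_yaml_path(path)) {
    yaml::write_yaml(spec, path, precision = 12)
  } else {
    writeLines(jsonlite::toJSON(spec, auto_unbox = TRUE, digits = I(12),
                                pretty = TRUE), path)
  }
  invisible(path)
}

#' Write a steady state to JSON
#' @param ss a [simulate_to_steady_state()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_steady_state <- function(ss, path) {
  stopifnot(inherits(ss, "steady_state"))
  obj <- list(x_ss = as.list(ss$x_ss), u_bf = as.numeric(ss$u_bf),
              residual_norm = ss$residual_norm, t_converged = ss$t_converged,
              method = ss$method, tol_ss = ss$tol_ss)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(12),
                              pretty = TRUE), path)
  invisible(path)
}

#' Read a steady state written by [write_steady_state()]
#' @param path JSON file path.
#' @return a `steady_state` object.
#' @export
read_steady_state <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(x_ss = unlist(obj$x_ss), u_bf = as.numeric(obj$u_bf),
                 residual_norm = obj$residual_norm,
                 t_converged = obj$t_converged, method = obj$method,
                 tol_ss = obj$tol_ss),
            class = "steady_state")
}

#' Write a linearization to JSON
#' @param lin a [linearize()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_linear_model <- function(lin, path) {
  stopifnot(inherits(lin, "linear_model"))
  obj <- list(A = unname(lin$A), B = unname(lin$B),
              species = names(lin$x_ss), input_names = colnames(lin$B),
              x_ss = as.numeric(lin$x_ss), u_bf = as.numeric(lin$u_bf),
              eigenvalues = list(re = Re(lin$eigenvalues), im = Im(lin$eigenvalues)),
              stable = lin$stable, hyperbolic = lin$hyperbolic)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(12),
                              pretty = TRUE), path)
  invisible(path)
}

#' Read a linearization written by [write_linear_model()]
#' @param path JSON file path.
#' @return a `linear_model` object.
#' @export
read_linear_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  A <- as.matrix(obj$A); B <- as.matrix(obj$B)
  if (is.null(dim(B)) || length(B) == 0) B <- matrix(0, nrow(A), 0)
  dimnames(A) <- list(obj$species, obj$species)
  colnames(B) <- obj$input_names
  structure(list(A = A, B = B,
                 x_ss = stats::setNames(as.numeric(obj$x_ss), obj$species),
                 u_bf = as.numeric(obj$u_bf),
                 eigenvalues = complex(real = obj$eigenvalues$re,
                                       imaginary = obj$eigenvalues$im),
                 stable = obj$stable, hyperbolic = obj$hyperbolic),
            class = "linear_model")
}

report_csv_table <- function(report) {
  m <- report$metrics
  data.frame(workflow_id = m$workflow, r_noise = m$r_noise, scope = m$scope,
             std_ratio_pct = m$std_ratio_pct, mre_pct = m$mre_pct, mse = m$mse)
}

#' Write a Monte Carlo report
#'
#' JSON keeps the full report (metrics plus run metadata); CSV mirrors the
#' standard results-table layout with columns `workflow_id`, `r_noise`,
#' `scope`, `std_ratio_pct`, `mre_pct`, `mse` — one row per workflow, noise
#' range and scope.
#'
#' @param report an `mc_report` from [run_workflow()] or
#'   [run_mc_experiment()].
#' @param path output path; `.csv` selects CSV, otherwise JSON.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mc_report"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(format(report_csv_table(report), digits = 12, trim = TRUE,
                            scientific = NA),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(metrics = report$metrics, n_failed = report$n_failed,
                meta = report$meta)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(12),
                                dataframe = "columns", pretty = TRUE), path)
  }
  invisible(path)
}

#' Read a Monte Carlo report written as JSON by [write_report()]
#' @param path JSON file path.
#' @return an `mc_report` object.
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(metrics = as.data.frame(obj$metrics), n_failed = obj$n_failed,
                 meta = obj$meta),
            class = "mc_report")
}

#' Plot the mean-relative-error growth trend
#'
#' Log-log plot of mean MRE versus noise range, one line per workflow, for
#' one scope. Approximately straight lines of slope near 2 reflect the
#' second-order character of the linearization error.
#'
#' @param report an `mc_report`.
#' @param scope `"all_states"` or `"readouts"`.
#' @param file optional PNG path; `NULL` draws on the active device.
#' @return invisibly, the plotted data.
#' @export
plot_error_trend <- function(report, scope = "readouts", file = NULL) {
  d <- report$metrics[report$metrics$scope == scope & report$metrics$mre_pct > 0, ]
  if (!nrow(d)) stop("nothing to plot: MRE is zero everywhere for this scope")
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 540)
    on.exit(grDevices::dev.off())
  }
  wfs <- sort(unique(d$workflow))
  graphics::plot(NA, xlim = range(d$r_noise), ylim = range(d$mre_pct),
                 log = "xy", xlab = "noise range r", ylab = "mean MRE (%)",
                 main = paste("Linearization error growth:", scope))
  for (i in seq_along(wfs)) {
    di <- d[d$workflow == wfs[i], ]
    di <- di[order(di$r_noise), ]
    graphics::lines(di$r_noise, di$mre_pct, type = "b", col = i, pch = 16)
  }
  graphics::legend("topleft", legend = paste("workflow", wfs),
                   col = seq_along(wfs), lty = 1, pch = 16, bty = "n")
  invisible(d)
}
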