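#' Configuration for the synthetic signaling-cascade generator
#'
#' Describes a layered receptor-ligand cascade in the style of the canonical
#' WNT pathway: extracellular ligands bind membrane receptors, the resulting
#' complexes recruit coreceptors, signal propagates through activation layers
#' and terminates in positive/negative readout pairs that share a precursor
#' (mimicking transcription-factor complexes with activating and repressing
#' partners).
#'
#' @param n_ligands,n_receptors,n_coreceptors counts of membrane-layer species.
#' @param n_readouts number of terminal readout species; must be even
#'   (positive/negative pairs).
#' @param depth total number of cascade layers: layer 1 is ligand-receptor
#'   binding, layer 2 coreceptor recruitment, further layers are first-order
#'   activation steps. Minimum 2.
#' @param density fraction in (0, 1] of allowed cross-layer binding pairs
#'   actually wired.
#' @param n_inputs number of exogenous inflow inputs; `NULL` (default) feeds
#'   every membrane species (ligands, receptors, coreceptors). Larger values
#'   add basal synthesis inflows to cascade species, in species order.
#' @param param_log10_range range of `log10` rate constants; constants are
#'   drawn log-uniformly from it.
#' @param input_lognormal `c(meanlog, sdlog)` of the log-normal base-input
#'   magnitudes used by [sample_base_inputs()] presets.
#' @param seed RNG seed; a fixed seed yields a byte-identical network.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_ligands = 4L, n_receptors = 3L, n_coreceptors = 1L,
                             n_readouts = 8L, depth = 3L, density = 0.5,
                             n_inputs = NULL, param_log10_range = c(-1, 1),
                             input_lognormal = c(0, 0.5), seed = 1L) {
  stopifnot(n_ligands >= 1, n_receptors >= 1, n_coreceptors >= 1,
            n_readouts >= 2, n_readouts %% 2 == 0,
            depth >= 2, density > 0, density <= 1,
            length(param_log10_range) == 2, diff(param_log10_range) >= 0,
            length(input_lognormal) == 2, input_lognormal[2] > 0)
  structure(list(n_ligands = as.integer(n_ligands),
                 n_receptors = as.integer(n_receptors),
                 n_coreceptors = as.integer(n_coreceptors),
                 n_readouts = as.integer(n_readouts),
                 depth = as.integer(depth), density = density,
                 n_inputs = if (is.null(n_inputs)) NULL else as.integer(n_inputs),
                 param_log10_range = as.numeric(param_log10_range),
                 input_lognormal = as.numeric(input_lognormal),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Preset generator configurations
#'
#' `"toy"` is a minimal cascade for fast examples, `"desk"` (the default
#' elsewhere) produces roughly 40 states with 8 inputs and 8 readouts, and
#' `"paper_scale"` reproduces the published WNT model's dimensions
#' (approximately 421 states, 60 inputs, 40 readouts) for benchmarking only.
#'
#' @param preset one of `"toy"`, `"desk"`, `"paper_scale"`.
#' @param seed RNG seed passed through to [generator_config()].
#' @return a `generator_config`.
#' @export
generator_preset <- function(preset = c("desk", "toy", "paper_scale"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    toy = generator_config(1L, 1L, 1L, n_readouts = 2L, depth = 2L, density = 1,
                           seed = seed),
    desk = generator_config(4L, 3L, 1L, n_readouts = 8L, depth = 3L, density = 0.5,
                            n_inputs = 8L, seed = seed),
    paper_scale = generator_config(7L, 7L, 2L, n_readouts = 40L, depth = 4L,
                                   density = 1, n_inputs = 60L, seed = seed)
  )
}

#' Generate a WNT-like layered cascade network
#'
#' Builds a mass-action [reaction_network()] from a [generator_config()]:
#' input-fed ligand/receptor/coreceptor species, ligand-receptor binding
#' complexes, coreceptor recruitment, optional first-order activation layers,
#' and terminal positive/negative readout pairs formed competitively from
#' shared precursor species. Every species carries a first-order degradation
#' reaction, so each state equation is a stable first-order filter driven by
#' the rest of the network and the structural decomposition of
#' [decompose_structural_form()] exists for all states. The topology is
#' acyclic (no feedback), which in practice yields hyperbolic, stable fixed
#' points for positive inputs.
#'
#' Rate constants are drawn log-uniformly over `10^param_log10_range` using
#' the config seed; output is deterministic for a fixed config.
#'
#' @param config a [generator_config()].
#' @return a [reaction_network()].
#' @export
generate_wnt_like_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_preserved_seed(config$seed, {
    ligands <- paste0("WNT", seq_len(config$n_ligands))
    receptors <- paste0("FZD", seq_len(config$n_receptors))
    coreceptors <- paste0("LRP", seq_len(config$n_coreceptors))
    species <- c(ligands, receptors, coreceptors)
    reactions <- list()
    add_rx <- function(reactants, products) {
      reactions[[length(reactions) + 1L]] <<- list(
        reactants = reactants, products = products,
        rate_param = paste0("k", length(reactions) + 1L))
    }

    # layer 1: ligand-receptor binding, thinned by density (>= 1 pair kept)
    pairs <- expand.grid(l = ligands, r = receptors, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(pairs)) <= config$density
    if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
    layer <- character()
    for (i in which(keep)) {
      cx <- paste0("CPX1_", i)
      species <- c(species, cx); layer <- c(layer, cx)
      add_rx(stats::setNames(c(1, 1), c(pairs$l[i], pairs$r[i])),
             stats::setNames(1, cx))
    }

    # layer 2: coreceptor recruitment by layer-1 complexes
    pairs2 <- expand.grid(c1 = layer, q = coreceptors, stringsAsFactors = FALSE)
    keep2 <- stats::runif(nrow(pairs2)) <= config$density
    if (!any(keep2)) keep2[sample.int(nrow(pairs2), 1L)] <- TRUE
    layer2 <- character()
    for (i in which(keep2)) {
      cx <- paste0("CPX2_", i)
      species <- c(species, cx); layer2 <- c(layer2, cx)
      add_rx(stats::setNames(c(1, 1), c(pairs2$c1[i], pairs2$q[i])),
             stats::setNames(1, cx))
    }
    layer <- layer2

    # deeper layers: first-order activation of every previous-layer species
    if (config$depth > 2L) {
      for (d in seq(3L, config$depth)) {
        nxt <- paste0("ACT", d - 2L, "_", seq_along(layer))
        species <- c(species, nxt)
        for (i in seq_along(layer))
          add_rx(stats::setNames(1, layer[i]), stats::setNames(1, nxt[i]))
        layer <- nxt
      }
    }

    # readout layer: shared precursors split into positive/negative readouts
    n_pairs <- config$n_readouts %/% 2L
    src <- layer[1L + (seq_len(n_pairs) - 1L) %% length(layer)]
    readouts <- character()
    for (t in seq_len(n_pairs)) {
      pre <- paste0("PRE", t); pos <- paste0("POS", t); neg <- paste0("NEG", t)
      species <- c(species, pre, pos, neg)
      add_rx(stats::setNames(1, src[t]), stats::setNames(1, pre))
      add_rx(stats::setNames(1, pre), stats::setNames(1, pos))
      add_rx(stats::setNames(1, pre), stats::setNames(1, neg))
      readouts <- c(readouts, pos, neg)
    }

    # universal first-order degradation guarantees the h1 lower bound
    for (s in species) add_rx(stats::setNames(1, s), numeric())

    n_inputs <- if (is.null(config$n_inputs))
      length(ligands) + length(receptors) + length(coreceptors) else config$n_inputs
    if (n_inputs > length(species))
      stop("configuration error: more inputs requested than species available")
    fed <- species[seq_len(n_inputs)]
    inputs <- stats::setNames(fed, paste0("u", seq_len(n_inputs)))

    lo <- config$param_log10_range[1]; hi <- config$param_log10_range[2]
    parameters <- stats::setNames(10^stats::runif(length(reactions), lo, hi),
                                  paste0("k", seq_along(reactions)))

    reaction_network(species = species, reactions = reactions,
                     parameters = parameters, inputs = inputs,
                     readouts = readouts)
  })
}

#' Draw rate constants from a log-uniform distribution
#'
#' Each entry is \eqn{10^v} with \eqn{v \sim \mathrm{Uniform}(a, b)}; the
#' default range `c(-1, 1)` spans two decades, `[0.1, 10]`.
#'
#' @param n number of constants.
#' @param seed RNG seed.
#' @param log10_range range of the uniform exponent.
#' @return numeric vector of length `n`.
#' @export
sample_parameters <- function(n, seed = 1L, log10_range = c(-1, 1)) {
  stopifnot(n >= 1)
  with_preserved_seed(seed, 10^stats::runif(n, log10_range[1], log10_range[2]))
}

#' Draw base input vectors from a log-normal distribution
#'
#' Input magnitudes are strictly positive and i.i.d. log-normal, emulating
#' basal synthesis rates fitted to expression-like data.
#'
#' @param n_samples number of input vectors.
#' @param n_inputs length of each vector.
#' @param mu,sigma meanlog and sdlog of the log-normal.
#' @param seed RNG seed.
#' @return list of `n_samples` numeric vectors of length `n_inputs`.
#' @export
sample_base_inputs <- function(n_samples, n_inputs, mu = 0, sigma = 0.5, seed = 1L) {
  stopifnot(n_samples >= 1, n_inputs >= 1, sigma > 0)
  with_preserved_seed(seed, {
    lapply(seq_len(n_samples), function(i) stats::rlnorm(n_inputs, mu, sigma))
  })
}
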