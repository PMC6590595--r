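#' Analytic toy fixtures with closed-form steady states
#'
#' Small reaction networks used throughout the package's tests and examples.
#' All have known steady states:
#'
#' * `decay1`: one species with first-order decay at rate 2 and an inflow,
#'   \eqn{\dot x = u - 2x}; steady state \eqn{x = u/2}.
#' * `bind2`: `A + B -> C` at rate 1, all three species degrade at rate 1,
#'   inflows feed `A` and `B`, readout `C`. For the symmetric input
#'   \eqn{u = (v, v)} the steady state solves \eqn{s^2 + s - v = 0} with
#'   \eqn{x_A = x_B = s} and \eqn{x_C = s^2}; at \eqn{v = 2}, \eqn{x = (1,1,1)}.
#' * `chain3`: linear cascade `A -> B -> C` (rates 1) with unit degradation
#'   of every species and an inflow into `A`; at \eqn{u = 4} the steady state
#'   is \eqn{(2, 1, 1)}.
#' * `affine_n`: a purely linear conversion chain of `n` species (no
#'   bimolecular reactions), inflows into the first two species, readout the
#'   last species. Its state Jacobian is constant, so a Taylor linearization
#'   is exact everywhere: the package's zero-error reference model.
#'
#' @param name one of `"decay1"`, `"bind2"`, `"chain3"`, `"affine_n"`.
#' @param n chain length for `affine_n` (ignored otherwise).
#' @return a [reaction_network()].
#' @export
make_toy_model <- function(name, n = 8L) {
  switch(name,
    decay1 = reaction_network(
      species = "X",
      reactions = list(list(reactants = c(X = 1), products = numeric(), rate_param = "k_deg")),
      parameters = c(k_deg = 2),
      inputs = c(u = "X"),
      readouts = "X"
    ),
    bind2 = reaction_network(
      species = c("A", "B", "C"),
      reactions = list(
        list(reactants = c(A = 1, B = 1), products = c(C = 1), rate_param = "k_bind"),
        list(reactants = c(A = 1), products = numeric(), rate_param = "k_degA"),
        list(reactants = c(B = 1), products = numeric(), rate_param = "k_degB"),
        list(reactants = c(C = 1), products = numeric(), rate_param = "k_degC")
      ),
      parameters = c(k_bind = 1, k_degA = 1, k_degB = 1, k_degC = 1),
      inputs = c(uA = "A", uB = "B"),
      readouts = "C"
    ),
    chain3 = reaction_network(
      species = c("A", "B", "C"),
      reactions = list(
        list(reactants = c(A = 1), products = c(B = 1), rate_param = "k_ab"),
        list(reactants = c(B = 1), products = c(C = 1), rate_param = "k_bc"),
        list(reactants = c(A = 1), products = numeric(), rate_param = "k_degA"),
        list(reactants = c(B = 1), products = numeric(), rate_param = "k_degB"),
        list(reactants = c(C = 1), products = numeric(), rate_param = "k_degC")
      ),
      parameters = c(k_ab = 1, k_bc = 1, k_degA = 1, k_degB = 1, k_degC = 1),
      inputs = c(uA = "A"),
      readouts = "C"
    ),
    affine_n = {
      n <- as.integer(n)
      if (n < 2L) stop("affine_n needs n >= 2")
      sp <- paste0("S", seq_len(n))
      rx <- list()
      pars <- numeric()
      for (i in seq_len(n - 1L)) {
        nm <- paste0("k_conv", i)
        rx[[length(rx) + 1L]] <- list(reactants = stats::setNames(1, sp[i]),
                                      products = stats::setNames(1, sp[i + 1L]),
                                      rate_param = nm)
        pars[nm] <- 1
      }
      for (i in seq_len(n)) {
        nm <- paste0("k_deg", i)
        rx[[length(rx) + 1L]] <- list(reactants = stats::setNames(1, sp[i]),
                                      products = numeric(), rate_param = nm)
        pars[nm] <- 1
      }
      reaction_network(species = sp, reactions = rx, parameters = pars,
                       inputs = stats::setNames(sp[1:2], c("u1", "u2")),
                       readouts = sp[n])
    },
    stop("unknown toy model '", name, "'")
  )
}
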