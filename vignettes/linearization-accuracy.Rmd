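---
title: "Linearization accuracy for mass-action reaction networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linearization accuracy for mass-action reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model class

`reactlin` works on deterministic mass-action reaction networks,

$$\frac{dx}{dt} = f(x, p, u) = N\, v(x, p) + B u, \qquad y = g(x) = x_{\mathrm{readouts}},$$

where $N$ is the stoichiometry matrix, $v$ the vector of mass-action reaction
rates, and the inputs $u \ge 0$ enter as zero-order inflows through a constant
0/1 incidence matrix $B$. Three structural restrictions are imposed by the
`reaction_network()` constructor and are load-bearing for everything else:

1. **At most bimolecular reactions, reactant stoichiometry at most one per
   species.** Every rate is $k$, $k x_i$, or $k x_i x_j$ with $i \ne j$. The
   right-hand side is therefore *bilinear* in the state: its third
   derivatives vanish identically, so the symmetric second difference
   $[f(x+dx) + f(x-dx) - 2f(x)]/2$ computes the discarded second-order Taylor
   term *exactly* (`hessian_error_indicator()`), not approximately.
2. **First-order self-loss for every species** (checked by
   `decompose_structural_form()`). Each state equation can then be written
   $\dot x_k = -x_k h_1(x_{-k}, p) + h_2(x_{-k}, p) + u_k$ with
   $h_1 > c_k > 0$ and $h_2 \ge 0$ on the nonnegative orthant: viewed in
   isolation, every state is a stable first-order filter driven by the rest
   of the network. This bound is enforced *statically* — the decomposition
   demands a degradation reaction whose rate depends on $x_k$ alone — because
   a pointwise check at one state vector would say nothing about the rest of
   the domain. Networks violating it (e.g. purely autocatalytic toys used to
   exercise the unstable branches of the diagnostics) can still be built and
   simulated; only the structural certificate is refused.
3. **Inputs as zero-order inflows.** Consequently $B$ is constant and
   $A(x) = \partial f/\partial x$ never depends on $u$, so the Taylor
   expansion has no input-nonlinearity remainder: the linearization error is
   purely a state-space phenomenon. `check_linearity_conditions()` verifies
   both properties numerically, which matters only when the `rate_modifier`
   extension hook deliberately injects input-dependent kinetics.

Positivity comes for free: at a zero crossing of $x_k$ the loss term
vanishes and $\dot x_k = h_2 + u_k \ge 0$, so trajectories started in the
nonnegative orthant stay there (up to integrator round-off, which we allow
to dip to about $-10\times$ the absolute tolerance before flagging).

## Linearization and the agreement system

At a steady state $f(x_{ss}, u_{bf}) = 0$, discarding all second- and
higher-order terms gives the deviation model
$\dot x_{dev} = A x_{dev} + B(u - u_{bf})$ with
$A = \partial f/\partial x|_{ss}$ assembled analytically from the reaction
list (exactness is tested against central finite differences). For a
step-like input with final value $u_f$, the linear prediction is one solve:

$$x_{dev,ss} = -A^{-1} B (u_f - u_{bf}).$$

`linearize()` caches the eigenvalues of $A$ and flags *hyperbolicity*
(no eigenvalue with zero real part — the precondition for the linearization
to share the local qualitative behavior of the nonlinear flow) and
*stability*. The real-part tolerance is $10^{-8}$ times the spectral radius:
purely a floating-point guard, since "zero real part" is not decidable
numerically at any fixed scale-free threshold.

Rather than simulating the two models separately and subtracting,
`build_agreement_system()` stacks them into one $2n$-state system started at
$[0; x_{ss}]$, whose Jacobian is block diagonal. This keeps both components
on the same adaptive time grid, makes $e(t) = x_{nonlin} - x_{dev} - x_{ss}$
start at exactly zero by construction, and gives the integrator the exact
block Jacobian. At the end, the steady-state slices are polished: the
deviation block by its exact linear solve, the nonlinear block by damped
Newton iteration on $f = 0$. On purely linear models (the `affine_n`
fixture) this drives the steady-state agreement error to solver precision —
the package's zero-error oracle.

Negative linear predictions are clipped to $[0, \infty)$ before scoring
(`clip_nonnegative()`): concentrations cannot be negative, and the nonlinear
model never produces them, so the unclipped sign excursions of the linear
model are pure artifact.

## Steady-state location

`simulate_to_steady_state()` integrates with a stiff variable-order,
variable-step method (deSolve's `lsoda`, supplied with the analytic
Jacobian) over doubling horizons until
$\|f\|_\infty < \mathrm{tol}_{ss}\,(1 + \|x\|_\infty)$, then switches to a
damped Newton iteration to polish the root. Defaults: `tol_ss = 1e-9`,
`rtol = 1e-8`, `atol = 1e-10`, `t_max = 1e7` time units. The mixed
absolute/relative criterion keeps the test meaningful for both near-zero and
large states; the Newton polish decouples the reported fixed point's
accuracy from the integration tolerance. Two failure modes are reported as
errors rather than results: exceeding `t_max` (an oscillatory or extremely
slow model) and a trajectory norm exceeding $10^9\times$ the initial scale
(an unstable model — linearization around such anchors is meaningless).

## The synthetic cascade generator

The generator emulates the *class* of receptor-ligand signaling models the
method targets, not any particular published topology: input-fed ligands,
receptors and coreceptors; ligand–receptor binding complexes thinned by a
`density` parameter; coreceptor recruitment; optional first-order activation
layers; and terminal positive/negative readout pairs formed competitively
from shared precursors (mimicking transcription-factor complexes with
activating and repressing partners). Every species degrades first-order, so
the structural certificate holds for all states by construction. The
topology is acyclic — no feedback — which in practice yields stable,
hyperbolic fixed points for positive inputs; this is a deliberate choice so
that the linearization's *preconditions* hold and the experiments measure
its *accuracy*, not its applicability.

Defaults follow the standard experimental setup for this problem: rate
constants log-uniform over $[10^{-1}, 10^1]$; base inputs i.i.d. log-normal
with `meanlog = 0`, `sdlog = 0.5` (no public input dataset exists to fit, so
a unit-median, moderately dispersed prior is used); the `desk` preset
produces roughly 30–40 states with 8 inputs and 8 readouts, and the
`paper_scale` preset reaches approximately 420 states, 60 inputs and 40
readouts. Inputs beyond the membrane species are basal-synthesis inflows to
cascade intermediates, the only way to reach input dimensions much larger
than the membrane layer. What the generator does **not** emulate: feedback
loops (e.g. destruction-complex regulation), conservation relations without
degradation, multi-compartment transport, and biologically calibrated rate
constants. Passing tests on generated networks therefore demonstrate the
method's behavior on stable acyclic mass-action cascades, and say nothing
about oscillatory or multistable regimes.

## The Monte Carlo accuracy workflow

For each base input sample: simulate from the origin to $x_{ss0}$; linearize
there; draw one direction vector $d_i \sim U[0,1]^m$ *per sample* and reuse
it across all noise ranges (so that levels are comparable within a sample);
perturb $u_i = (1 + r - 2rd_i) \circ u_{bf,i}$, which confines every
component to $[1-r, 1+r]$ times its base value; run the agreement system;
clip; score. Metrics per sample and scope (all states, or readouts only):

* $\mathrm{MSE} = \overline{(x_{ss,lin} - x_{ss,nonlin})^2}$,
* $\mathrm{MRE} = \overline{|x_{ss,lin} - x_{ss,nonlin}| / x_{ss,nonlin}}$
  in percent,
* $\mathrm{std}(e)/\mathrm{std}(x_{diff})$ in percent, with
  $x_{diff} = x_{ss,nonlin} - x_{ss0}$ — the fraction of the response's
  spread the linearization misses.

Two conventions required a decision. **Pooling order:** components are
averaged within a sample first, then samples averaged arithmetically; this
weights every input condition equally regardless of how many components
responded. **Denominator guard:** components whose nonlinear steady state
falls below $10^{-9}\times$ the scope's largest component are excluded from
the MRE (and counted). A state that decays to (numerical) zero while the
clipped linear prediction sits at zero would otherwise contribute a
$0/\epsilon$ term that dominates the mean without carrying information; the
exclusion count keeps the adjustment visible. Only when *all* scope
components are zero is the metric declared undefined.

The error-growth trend is summarized by the least-squares slope of
$\log \mathrm{MRE}$ vs $\log r$. Because the leading error term is the
quadratic Taylor remainder, the slope is expected (and tested) to lie near
2; an exactly linear model reports `exact_linear` instead of a slope, with
"numerically zero" meaning MRE below $10^{-9}$% at every level.

Experiment defaults are sized for a desk: 4 parameter vectors × noise ranges
{10%, 25%, 50%} × 25–50 input samples; the per-workflow parameter vectors are
fresh log-uniform draws on a fixed topology, and the same base-input set is
shared across workflows.

## Stability diagnostics

The flow map $\Phi$ over one sampling period $T_s$ is realized by
integrating the ODE, and its Jacobian $J(\Phi, x)$ by the variational matrix
ODE $\dot M = J(x(t)) M$, $M(0) = I$ — not by finite differences, which are
ill-conditioned for stiff systems. For linear time-invariant models the map
is computed exactly as $e^{A T_s}$ (`Matrix::expm`; its Padé implementation
is accurate to machine precision, which the $10^{-6}$-level tolerances on
the oscillator tests actually require). The local Lyapunov exponent at $x$
in direction $y$ is $\ln\|J(\Phi, x) y\| / T_s$; the global estimate
propagates the direction along the trajectory and averages per-step growth.
The default $T_s = 0.1/\rho(J)$ resolves the fastest mode.

`contraction_check()` evaluates the spectral norm of $J(\Phi, x)$ at
user-supplied sample points; $c_{\max} < 1$ is the sufficient (Banach)
condition for a unique fixed point in the sampled region. Two caveats are
by design: the condition is *sufficient*, and for non-normal Jacobians the
spectral norm exhibits transient growth — at short $T_s$ a perfectly stable
anchor can show $c_{\max} > 1$. The CLI's `diagnose` command therefore uses
$T_s = 5/|\mathrm{Re}\,\lambda_{\max}|$ (several slow time constants), while
the library function leaves $T_s$ explicit. Euclidean norms are used
throughout the diagnostics.

`input_sensitivity_compare()` contrasts $S = -J(x)^{-1}B$ at the anchor and
at the post-perturbation fixed point (spectral-norm difference, absolute and
relative): a large drift means the frozen linearization responds differently
to further input changes than the nonlinear model would.

## Iterative relinearization

The piecewise scheme advances the frozen-Jacobian linear model exactly over
each increment,

$$x_{k+1} = x_k + A_k^{-1}\left(e^{A_k \Delta t} - I\right) f(x_k, u),$$

recomputing $A_k$ at every step, and stops when successive iterates differ
by less than `tol` in the max norm. Because each step is the exact solution
of the local linear model, the iteration's fixed point satisfies
$f(x) = 0$ *for every* $\Delta t$ — the converged endpoint is the nonlinear
steady state itself, and a constant Jacobian collapses the scheme to the
single-solve prediction (with $\Delta t = \infty$ each step is a full Newton
step). The increment therefore does not control the endpoint; it controls
how closely the iterate path tracks the nonlinear *trajectory*, with a
tracking error that shrinks roughly quadratically as $\Delta t$ halves.
That is the property the tests assert, alongside endpoint convergence.

## The inverse (dose-design) problem

`required_input_deviation()` inverts the one-solve prediction: given a
target state deviation $\Delta x$, solve $B \Delta u = -A \Delta x$ for the
input change. With more states than inputs the system is generally
inconsistent, so the minimum-norm least-squares solution (pseudoinverse) is
returned together with the residual norm — a zero residual means the target
is exactly reachable through the available inflows; a large one flags an
unreachable target rather than silently returning a poor compromise.

## Numerical choices, summarized

| quantity | default | unit | rationale |
|---|---|---|---|
| `tol_ss` | 1e-9 | relative | steady-state residual, mixed abs/rel test |
| `rtol` / `atol` | 1e-8 / 1e-10 | — | stiff integration; positivity slack is 10×`atol` |
| divergence guard | 1e9 × initial scale | — | abort visibly on unstable models |
| hyperbolicity `tol_re` | 1e-8 × spectral radius | 1/time | floating-point guard on Re λ = 0 |
| condition-number cap | 1e12 | — | refuse one-solve predictions at ill-conditioned anchors |
| `eps_den_factor` | 1e-9 × max component | — | MRE denominator guard |
| Lyapunov `T_s` | 0.1 / ρ(J) | time | resolve the fastest mode |
| relinearization `tol` | 1e-10 | conc | endpoint stationarity |

Dense factorizations (`solve`, SVD) are used throughout: at a few hundred
states the matrices are small, and conditioning is checked where a solve
feeds a reported prediction.

## Known limitations

* Only mass-action kinetics; saturating rate laws break both the structural
  certificate and the exactness of the second-difference Hessian.
* The generator's acyclic topology cannot produce oscillatory or multistable
  models, so the diagnostics' negative branches are exercised by constructed
  counterexamples (a pure rotation, an autocatalytic toy) rather than by
  generated networks.
* Metrics are defined at steady state; transient agreement is observable in
  `simulate_agreement()`'s time courses but not aggregated.
* The contraction check samples a finite set of points; it certifies nothing
  between samples.
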