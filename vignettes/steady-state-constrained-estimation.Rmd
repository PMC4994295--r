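---
title: "Estimating ODE model parameters under steady-state constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ODE model parameters under steady-state constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssfit)
```

## The estimation problem

Perturbation experiments stimulate a biochemical system that rests at a
steady state of its unperturbed dynamics and record the time-resolved
response. For an ODE model

$$\frac{dx}{dt} = f(x,\theta,u), \qquad y = h(x,\theta,u),$$

with states $x$, parameters $\theta$, inputs $u$ and observables $y$,
the initial condition of experiment $e$ is the steady state of the
control input $u_c^e$:

$$0 = f(x_s^e, \theta, u_c^e).$$

Measurements $\bar y_{ij}^e = y_i^e(t_j) + \varepsilon_{ij}^e$ with
independent Gaussian noise $\varepsilon_{ij}^e \sim
\mathcal N(0, (\sigma_{ij}^e)^2)$ lead to the constrained
maximum-likelihood problem

$$\min_{\theta,\,x_s^1,\dots,x_s^E}\;
J = \tfrac12 \sum_{e,j,i}
\left(\frac{\bar y_{ij}^e - y_i^e(t_j,\theta,x_s^e)}{\sigma_{ij}^e}\right)^2
\quad\text{s.t.}\quad f(x_s^e,\theta,u_c^e) = 0 .$$

The constraint couples the initial conditions to the parameters along a
nonlinear *steady-state manifold*. Standard constrained optimizers must
crawl along this manifold, which is the root of their poor convergence
on such problems. `ssfit` implements two methods that exploit the
manifold's geometry — its tangent (the steady-state sensitivity) and the
exponential stability of the steady state — next to the two standard
baselines.

When noise scales are estimated rather than known, the normalizing
terms $\sum \log(\sqrt{2\pi}\sigma)$ are included in $J$ (they matter
for the likelihood value and hence for BIC/AIC); with all $\sigma$
fixed they are an optimization-invariant constant and are omitted.

## Manifold geometry

Two quantities drive everything:

* the forward sensitivities $S(t) = \partial x/\partial\theta$, which
  obey $\dot S = (\partial f/\partial x) S + \partial f/\partial\theta$
  and are integrated alongside the states
  (`simulate_trajectory(..., sensitivities = TRUE)`), together with the
  initial-condition sensitivities $\partial x/\partial x_0$;
* the steady-state sensitivity, obtained from the stationary
  sensitivity equation as the linear solve
  $S = -(\partial f/\partial x)^{-1}\,\partial f/\partial\theta$
  (`steady_state_sensitivity()`). Off the manifold the Jacobian need
  not be invertible and the Moore–Penrose pseudoinverse variant
  $\hat S = -(\partial f/\partial x)^{+}\,\partial f/\partial\theta$
  is used (`steady_state_sensitivity_pinv()`, relative singular-value
  cutoff $10^{-12}$); where the Jacobian is invertible the two agree.

The total ("reduced") objective gradient is the chain rule
$\mathrm{d}J/\mathrm{d}\theta = \partial J/\partial\theta +
\sum_e (\partial J/\partial x_s^e)\, S_e$ (`reduced_gradient()`), and
integrating $\mathrm{d}x_s/\mathrm{d}r = S\,\Delta\theta$ continues a
steady state along a parameter path (`steady_state_continuation()`).

## The four local methods

**Unconstrained (gold standard).** When an analytic steady-state map
$x_s(\theta,u)$ exists it eliminates the constraint; a bounded
quasi-Newton optimizer (L-BFGS-B) minimizes
$\theta \mapsto J(\theta, x_s(\theta,u_c^1),\dots)$ with the reduced
gradient. For models without a closed form the package substitutes a
high-accuracy numeric steady state (residual $10^{-12}$); this keeps
the baseline available for, e.g., the Raf/MEK/ERK model, whose closed
form we do not carry.

**Constrained (state of the art).** The full problem over
$(\theta, x_s^1,\dots,x_s^E)$ with $E$ vector equality constraints. No
installed NLP solver handles nonlinear equality constraints, so the
package delegates the bound-constrained subproblems to L-BFGS-B inside
a standard augmented-Lagrangian outer loop (multiplier update
$\nu \leftarrow \nu + \rho c$, penalty growth $\times 10$ when the
constraint norm fails to shrink by 4, $\rho \le 10^8$). Objective and
constraint Jacobians are analytic.

**Hybrid (retraction).** Each objective evaluation retracts the
proposed point onto the manifold: the steady states are recomputed by
`compute_steady_state()` warm-started at the previous iterate's values,
to residual accuracy $\varepsilon_{\mathrm{tol}}$ ($10^{-9}$ by
default, $10^{-13}$ for the Raf application's tighter demands), and J
plus the reduced gradient of the retracted point are handed to the same
L-BFGS-B as above. The problem dimension drops to $n_\theta$. A failed
retraction returns a large finite penalty ($10^{10}$, zero gradient) so
the line search can back off rather than abort.

**Simulation-based (continuous analogue).** The flow

$$\frac{d\theta}{dr} = -g, \qquad
\frac{dx_s^e}{dr} = \hat S_e \frac{d\theta}{dr}
 + \lambda f(x_s^e,\theta,u_c^e)$$

is integrated in an artificial variable $r$ until
$\max(\|d\theta/dr\|, \|dx_s/dr\|) < \varepsilon_{\mathrm{tol}}$
(default $10^{-6}$). Gradient descent uses $g = \mathrm{d}J/\mathrm{d}\theta$;
Newton-type descent uses $g = (F + \mu I)^{-1} \mathrm{d}J/\mathrm{d}\theta$
with the Fisher information $F$ (a PSD first-order approximation of the
Hessian) and regularization $\mu = 10^{-4}\,\mathrm{tr}(F)/n_\theta$,
floored at $10^{-8}$, since no canonical value exists. One sign
convention in the source literature composes to an *ascent* direction
if read literally; the package implements the descent-producing sign
($d\theta/dr = -\mathrm{d}J/\mathrm{d}\theta$), which is what makes $J$
decrease along the flow. The $\lambda f$ term retracts off-manifold
states using the stability of the steady state; $\lambda = 100$ by
default — large enough for a clear two-phase behavior (fast collapse
onto the manifold, then descent along it), small enough that the flow,
while stiff, remains integrable. With $\lambda = 0$ and an on-manifold
start the flow provably stays on the manifold, which the test suite
verifies numerically.

### Numerical realization of the flow

The flow is stiff (time-scale ratio $\sim \lambda/\mu_{\min}$ with
$\mu_{\min}$ the smallest curvature of the objective valley), so it is
integrated with an adaptive stiff solver (`deSolve`'s lsoda) over a
geometric grid of checkpoints, one decade of flow length at a time, and
the stopping criterion is tested at each checkpoint. The corrector is
supplied with an analytic approximate flow Jacobian — the Gauss–Newton
curvature $-F$ in the $\theta$ block and the retraction blocks
$\lambda\,\partial f/\partial x$ in the states, the terms that carry
the stiffness — so no finite differences of the expensive right-hand
side are ever taken. The flow variable is non-dimensionalized by the
initial flow speed, making flow-length budgets comparable across
problems (the trajectory itself is unchanged; the stopping criterion is
tested on the physical speeds).

Each right-hand side evaluation requires one forward-sensitivity
simulation per experiment; for the built-in models these run through
compiled C implementations of the augmented sensitivity system and
through the package's own embedded integrators — an explicit
Dormand–Prince 5(4) pair (`ode_method = "rk45c"`) and an L-stable
two-stage Rosenbrock-W method (`"roswc"`) — which, unlike external ODE
libraries, may be invoked from inside the outer solver's right-hand
side (FORTRAN solvers are not re-entrant). The flow integration uses
relative tolerance $10^{-8}$ by default; tolerances and the flow-length
budget (`r_max_decade`) are plain settings.

Bounds are handled by clipping: an outward-pointing velocity component
at an active bound is set to zero. The flow itself is the unbounded
object; clipping only prevents escape from the admissible box.

### Steady-state computation

`compute_steady_state()` implements three strategies. "simulate"
integrates the control system over horizons $\tau\,10^k$,
$k = 0,1,\dots$, with $\tau$ the reciprocal of the slowest local decay
rate (from the Jacobian's eigenvalues) when computable and 1 otherwise
— the schedule is ours, chosen so that each horizon probes one decade
of relaxation. "newton" is a damped Newton–Raphson iteration (step
halving, at most 30 halvings, accepting only residual decrease; a
singular Jacobian falls back to simulation). "hybrid" (default)
simulates to the vicinity (residual $\le \max(10^{-4},
\sqrt{\mathrm{tol}})$) and polishes with Newton. A guess already
satisfying the tolerance is returned unchanged, making the operation
idempotent.

## Parameter scales and bounds

All optimization happens on a per-parameter scale: `log10` for
positive biochemical rates (gradients and Fisher information are
chain-ruled accordingly) with natural-scale bounds $[10^{-5},10^5]$
for the NGF-ERK model and $[10^{-2},10^2]$ for the Raf/MEK/ERK model —
rates and time constants outside two decades of the models' time
scales of minutes are indistinguishable on the experimental designs
considered, and admitting them only seeds local optima. The conversion process uses the linear scale
with bounds $[10^{-2},10^2]$: its printed continuous analogue evolves
in the linear parameters and the textbook start $(1,1)$ is linear-scale
territory.

## The model zoo

* `build_conversion_model()`: one-state reversible conversion
  $A \rightleftharpoons B$ under mass conservation,
  $dx/dt = \theta_2 - (\theta_1 u + \theta_2)x$, with analytic steady
  state $x_s = \theta_2/(\theta_1 u + \theta_2)$ — the didactic test
  case with everything available in closed form.
* `build_ngf_erk_model()`: two-state NGF→TrkA→ERK cascade with
  composite parameters $k_3[\mathrm{TrkA}]_0$, $s[\mathrm{ERK}]_0$
  (products of rates and total abundances are the identifiable
  combinations) and estimated noise variance $\sigma^2$ as the seventh
  parameter. Closed-form steady state, exponentially stable for all
  positive parameters.
* `build_raf_mek_erk_model(hypothesis)`: three-state Raf→MEK→ERK
  cascade in relative phosphorylation levels, released from S-phase
  arrest at $t=0$ via the transient drive
  $k_{1,\max}(t) = k_{1,0} + k_{1,1}(1 - e^{-t/\tau_1})e^{-t/\tau_2}$,
  with Raf- and MEK-inhibitor inputs acting through
  $K_2/(K_2+[\mathrm{sora}])$ and $K_3/(K_3+[\mathrm{UO126}])$.
  Hypothesis H1 adds negative feedback of pERK on Raf phosphorylation,
  $\xi = K_1/(K_1 + x_3)$, where $K_1$ is expressed relative to the
  total ERK abundance (the identifiable composite in relative states);
  H2 sets $\xi = 1$, so H1 nests H2 as $K_1 \to \infty$. Observables
  are per-blot scaled pMEK and pERK levels (Western blots only carry
  relative, blot-specific scales). The steady-state machinery always
  evaluates the vector field frozen at $t = 0$, where
  $k_{1,\max}(0) = k_{1,0}$ — the constraint belongs to the arrested
  (autonomous) system. No closed-form steady state is attached; it is
  computed numerically.

For all three models the vector field, Jacobians and the augmented
forward-sensitivity system are additionally implemented in C; the R
closures remain as the reference implementation (the test suite checks
both paths against each other) and as the template for user-defined
models, which work unmodified through the same interface.

## What the synthetic data emulate — and what they do not

`generate_dataset()` reproduces the statistical structure of the
measurement model: noise-free trajectories started at the
control-condition steady state (computed to residual $10^{-12}$),
plus independent Gaussian noise of known scale added on the observable
scale, i.e. after scaling parameters. `toy_fixture()` is the printed
conversion-process configuration ($\theta = (4,1)$, $u_c = 1$,
$u = 0.4$, $t = (0, 0.1, 0.5, 1, 2)$, unit variance).
`raf_fixture()` emulates the Western-blot study design: three
conditions (control, sorafenib, UO126) released from the same arrest
steady state, observed as scaled relative pMEK/pERK at nine time
points over two hours. Its generating parameters are documented
package constants chosen once: rates of order $0.03$–$0.6\,
\mathrm{min}^{-1}$ so the release transient spans the sampling window,
inhibitor doses of five times the respective inhibition constants, a
feedback constant $K_1 = 0.2$ (strong feedback well inside the
identifiable range), scaling factors 2 and noise $\sigma = 0.05$ —
about 3–5 % of the dynamic range, a realistic quantitative-blot error.

Real Western-blot data additionally carry log-normal error components,
between-blot correlations and occasional saturation; none of these are
modeled. Passing the synthetic recovery and model-selection tests
therefore demonstrates correctness of the estimator under its own
assumptions, not robustness to the full error structure of blot data.

## Multi-start evaluation and model selection

`run_multistart()` draws one Latin hypercube start set per study
(`sample_starts()`, stratified per dimension on the optimization
scale) and reuses it across methods, so method comparisons share
identical starts; random state starts for the constrained and
simulation-based methods come from the same seeded stream. A start
counts as converged when (i) its final point is feasible — every
constraint residual below `eps_feasible` ($10^{-6}$) — and (ii) the
likelihood-ratio test cannot reject its final value against the best
*feasible* value found:
$2(J - J_{\mathrm{best}}) \le \chi^2_{1-\alpha}(\mathrm{df})$ with
$\alpha = 0.05$. Restricting the reference to feasible points matters:
an optimizer that relaxes the constraint can report an objective below
the constrained optimum without having solved the problem, and the
constrained baseline does exactly that on hard instances. The degrees of freedom are configurable and default
to df = 1 — the comparison is between two point estimates of the same
model. When several methods are evaluated jointly, $J_{\mathrm{best}}$
is the global best across methods.

`consistency_check()` evaluates the two steady-state diagnostics at a
run's final point: the solver's own criterion
$\|f(x_s,\theta,u_c)\|_2 < \varepsilon_f$ and the actual steady-state
error $\|x_s - x_s(\theta,u_c)\|_2 < \varepsilon_x$ against the
analytic map where available and a residual-$10^{-12}$ numeric
reference otherwise (both tolerances default to $10^{-6}$). For the
unconstrained method the two are identical by construction; for a
trustworthy optimizer they should agree.

For the nested Raf hypotheses, `select_raf_hypothesis()` implements the
comparison protocol: each hypothesis is fitted from the most promising
Latin hypercube points (a cheap objective pre-scan of a larger cloud
selects them), and additionally from the other hypothesis's best fit —
H1 with the feedback constant embedded at its upper bound (which
reproduces H2's dynamics exactly, so J(H1) can never lose to J(H2) by
local-optimum luck) and at a moderate value off the flat weak-feedback
direction; H2 from H1's best with the feedback constant dropped.

`information_criteria()` computes
$\mathrm{BIC} = 2J + n_p \ln n$ and $\mathrm{AIC} = 2J + 2 n_p$ from
the full negative log-likelihood. On synthetic Raf data generated
under H1 with strong feedback, fitting both hypotheses and taking
$\Delta\mathrm{BIC} = \mathrm{BIC}(\mathrm{H2}) -
\mathrm{BIC}(\mathrm{H1})$ yields a large positive preference for H1 —
the H2 model cannot reproduce the UO126-induced *increase* of pMEK,
which under feedback is explained by the drop in pERK weakening the
feedback. On H2-generated data the two fits coincide up to the
nesting, and ΔBIC reduces to (at most) the penalty difference of one
extra parameter.

## Problem sizes and budgets used by the test suite

The package's own studies are desk-scale by design: the toy recovery
runs all five method variants once; the convergence-ordering study
uses 50 common Latin hypercube starts on the synthetic Raf problem
(per-fit budgets of 200 L-BFGS-B iterations, 4 augmented-Lagrangian
outer rounds, one normalized decade of flow length with a 10 s
per-run cap) plus a 50-start toy study; the model-selection study runs
three seeds each of H1- and H2-generated data, fitting each hypothesis
from the 3 best of 40 objective-screened Latin hypercube points plus
the nested cross warm starts described above. These sizes
were chosen so the full suite completes in minutes while every
qualitative claim remains exercised; all of them are plain function
arguments, and nothing prevents running the same studies at larger n.

## Known limitations

* Unique, exponentially stable steady states are assumed throughout;
  conservation relations that render the Jacobian singular surface as
  an explicit error from `steady_state_sensitivity()` (condition
  estimate $>10^{12}$) rather than being eliminated automatically.
* No adjoint or second-order sensitivities; the Fisher information
  stands in for the Hessian.
* Gaussian, independent noise only.
* The likelihood-ratio convergence classification with df = 1 is a
  convention; any df can be passed.
* Wall-clock timings are recorded but never asserted: they are
  hardware facts, not science.
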