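# ssfit — ODE parameter estimation under steady-state constraints

Perturbation experiments stimulate a biochemical system that rests at a
steady state of its unperturbed dynamics. Fitting an ODE model

dx/dt = f(x, θ, u),  y = h(x, θ, u)

to such data is a constrained maximum-likelihood problem: the initial
condition of each experiment *e* must satisfy the steady-state
constraint f(x_s^e, θ, u_c^e) = 0 of its control input, so the
optimizer has to move along a nonlinear manifold of parameter–state
pairs. Generic constrained solvers converge poorly there; closed-form
steady states, which would eliminate the constraint, rarely exist.

`ssfit` is for modelers in systems biology who fit kinetic models to
time-resolved perturbation data. It implements two manifold-aware local
methods —

* **hybrid optimization**: every objective evaluation retracts the
  iterate onto the manifold by a warm-started steady-state computation
  (simulation plus Newton–Raphson polishing) and supplies the reduced
  gradient dJ/dθ = ∂J/∂θ + Σ_e (∂J/∂x_s^e) S_e, with the steady-state
  sensitivity S = −(∂f/∂x)⁻¹ ∂f/∂θ;
* **simulation-based optimization**: a continuous analogue — an ODE in
  an artificial flow variable whose equilibria are the local optima —
  with gradient or Newton-type (Fisher-information) descent, stabilized
  off the manifold by a retraction term λ·f and the pseudoinverse
  sensitivity Ŝ = −(∂f/∂x)⁺ ∂f/∂θ;

— next to unconstrained (analytic steady state; the gold standard) and
augmented-Lagrangian constrained baselines, plus forward sensitivity
analysis, a Latin-hypercube multi-start harness with likelihood-ratio
convergence classification and steady-state consistency diagnostics,
BIC/AIC model comparison, and a synthetic-data generator. Three models
ship with the package: a reversible conversion process, NGF-induced ERK
phosphorylation, and Raf/MEK/ERK signaling after release from S-phase
arrest with and without negative feedback (hypotheses H1/H2).

## Worked example

Recover the conversion-process parameters θ = (4, 1) from noise-free
data generated at the control steady state (u_c = 1) and observed under
the perturbation u = 0.4:

```r
library(ssfit)

model <- build_conversion_model()
data  <- toy_fixture()        # t = (0, 0.1, 0.5, 1, 2), sigma = 1

fit <- optimize_hybrid(model, data, theta0 = c(1, 1), eps_tol = 1e-9)
fit
#> <ssfit_run> method=hybrid, J=2.26721e-18, status=converged
#>   theta (natural):  4, 1
#>   max constraint residual: 0; 56 ODE sims; 0.05s

flow <- optimize_simulation_based(model, data, theta0 = c(1, 1),
                                  xs0 = list(0.9), lambda = 100,
                                  descent = "gradient")
round(flow$final$theta_natural, 4)
#> [1] 3.9959 0.9991
```

The hybrid method lands on the optimum with the final states exactly on
the steady-state manifold (residual below the retraction accuracy);
the continuous analogue first collapses onto the manifold (phase 1,
driven by λ·f) and then descends along it, stopping when the flow speed
max(‖dθ/dr‖, ‖dx_s/dr‖) falls below 10⁻⁶ — the remaining ≈4·10⁻³
parameter error is the width of the objective valley at that stopping
tolerance.

Model comparison on synthetic Raf/MEK/ERK data generated under the
feedback hypothesis:

```r
d1  <- raf_fixture("H1", feedback_strength = 0.05, seed = 1)
sel <- select_raf_hypothesis(d1, n_starts = 3, seed = 1001)
sel$delta_bic          # BIC(H2) - BIC(H1)
#> [1] 73.92884
```

Both hypotheses are fitted with the hybrid method from a common
objective-screened start set plus nested cross warm starts;
BIC = 2J + k log n then prefers the feedback hypothesis decisively
(ΔBIC of order 10²; on H2-generated data the difference collapses to
at most the one-parameter penalty).

A command-line entry point wraps the same functions:

```sh
Rscript inst/cli/ssfit.R generate --fixture toy --out toy.tsv
Rscript inst/cli/ssfit.R fit --method hybrid --model conversion \
    --data toy.tsv --start 1,1 --out fit.json
Rscript inst/cli/ssfit.R multistart --model conversion --data toy.tsv \
    --methods unconstrained,hybrid,sim-gradient --n-starts 10 --seed 1
```

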