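---
title: "Modelling a Michaelis-Menten micro-disk biosensor: methods and design choices"
author: "microdisk package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a Michaelis-Menten micro-disk biosensor: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdisk)
```

## The model

An enzyme-coated micro-disk electrode is modelled as a hemisphere of radius
$r_0$ carrying an enzyme film out to radius $r_1$. Substrate diffuses in
from the bulk, is converted by the immobilized enzyme following
Michaelis-Menten kinetics, and the product (hydrogen peroxide) diffuses
both outward and to the electrode, where it is consumed amperometrically.
At steady state, in spherical symmetry, the dimensionless concentrations
$S(R)$ (substrate) and $H(R)$ (peroxide) on $R \in [1, q]$, $q = r_1/r_0$,
satisfy

$$
S'' + \frac{2}{R} S' - \frac{\gamma_E\, S}{1 + \alpha S} = 0,
\qquad
H'' + \frac{2}{R} H' + \frac{\gamma_S\, S}{1 + \alpha S} = 0,
$$

with $S'(1) = 0$, $H(1) = 0$ (electrode surface) and $S(q) = 1$,
$H(q) = 0$ (outer film boundary). The dimensionless groups are

* $\gamma_E = k_{cat} C_E r_0^2 / (D_S K_M)$ and
  $\gamma_S = k_{cat} C_E r_0^2 / (D_H K_M)$ — Thiele-modulus-like
  reaction-diffusion parameters comparing enzymatic turnover with substrate
  and peroxide diffusion; their ratio equals $D_H / D_S$.
* $\alpha = C_S^*/K_M$ — the saturation parameter. $\alpha \to 0$ gives
  first-order kinetics, $\alpha \to \infty$ the saturated zero-order
  regime where the local rate tends to $\gamma_E/\alpha$.
* $q = r_1/r_0$ — film thickness relative to the electrode.

Two conventions are worth making explicit because the model statement
leaves them open. First, the peroxide concentration scale: we take
$C_H^* = C_S^*$, the unique choice under which the peroxide balance keeps
the same dimensionless rate group as the substrate balance. Second, in the
reaction scheme the reverse binding rate is the constant entering
$K_M = (k_{-1} + k_{cat})/k_1$; `dimensional_params()` names it `k_rev`
and enforces that identity when the elementary constants are supplied.

### The harmonic-combination identity

Multiplying the substrate equation by $\gamma_S$, the peroxide equation by
$\gamma_E$, and adding cancels the nonlinear rate term, so
$W = \gamma_S S + \gamma_E H$ satisfies the radial Laplace equation and
must equal $a + b/R$. Matching $H(1) = H(q) = 0$ gives
$b = \gamma_S\, q\, (S(1) - 1)/(q - 1)$ and $a = \gamma_S S(1) - b$. The
package exploits this twice: `reconstruct_peroxide_harmonic()` computes
$H$ from a solved $S$ without touching a linear solver, and
`harmonic_invariant_residual()` measures how far any profile strays from
the identity — an internal consistency check that involves no exact
solution. `solve_profile()` computes $H$ both ways by default and warns if
they disagree beyond `check_tol`.

## The reference solver

`solve_substrate()` discretizes the substrate equation on a uniform grid
with second-order central differences; the no-flux condition at $R = 1$
uses a second-order one-sided (3-point) stencil and the outer condition is
an exact Dirichlet row. The nonlinear system is solved by damped Newton
iteration with the analytic tridiagonal-plus-corner Jacobian (the rate
derivative is $\gamma_E/(1+\alpha s)^2$), starting from $S \equiv 1$. If
the plain solve stalls, $\gamma_E$ is ramped geometrically over
`continuation_steps` stages. The peroxide problem is linear given $S$ and
is solved in one sparse tridiagonal pass.

Numerical details that matter:

* The Newton residual is evaluated in *stencil* form (each interior row
  scaled by $h^2$), so the `newton_tol` max-norm (default $10^{-12}$) is
  meaningful at any grid resolution; in raw operator units the rounding
  floor grows like $1/h^2$ and a fixed tolerance would be unattainable on
  fine grids.
* Each Newton and peroxide linear solve applies one pass of iterative
  refinement. The discrete Green's function amplifies the factorization's
  backward error by $O(n^2)$; without refinement the two independent $H$
  computations agree only to $\sim 10^{-7}$ at $n = 4001$, with it they
  agree to $\sim 10^{-12}$.
* Newton iterations continue past `newton_tol` while the residual still
  improves (the extra solves are $O(n)$), so solutions sit at the rounding
  floor rather than just inside the tolerance.
* Defaults: $n = 4001$ for reference-quality runs (matching the dataset
  sizes 1143 and 1251 when emulating the study grids), `newton_tol`
  $10^{-12}$, damping $0.5$, at most 50 iterations, 8 continuation steps.

Correctness is established against two closed-form limits rather than
against another solver: the exact first-order solution
(`first_order_exact()`, valid at $\alpha = 0$, where $u = RS$ linearizes
the problem) and the saturated zero-order profile
(`saturated_limit_profile()`, valid for $\alpha S \gg 1$). The observed
convergence rate against the first-order oracle is $h^2$ (log-log slope
$-2.0$ over $n = 251$ to $2001$).

### Degenerate inputs

$\gamma_E = 0$ short-circuits to $S \equiv 1$; $\gamma_S = 0$ yields
$H \equiv 0$. `reconstruct_peroxide_harmonic()` refuses $\gamma_E = 0$
(the reconstruction divides by it) and directs the caller to the linear
solve. In deeply saturated cases the film can deplete ($S(1)$ at the
rounding floor); profile values are reported as computed, never clamped.

## The published closed forms

`madm_profiles()`, `ham_profiles()` and `hpm_profiles()` implement
low-order series approximations from the biosensor literature (modified
Adomian decomposition, homotopy analysis with control parameter $h$, and
homotopy perturbation). Three deliberate choices:

* The formulas are evaluated *exactly as published*, even where they leave
  the physical range $0 \le S \le 1$ (e.g. the HAM series at $h = -1$
  gives $S(1) = 1 - a(q-1)^2/2 < 0$ once $a = \gamma_E/(1+\alpha)$ is
  large). Validity is reported, not silently corrected, because the point
  of carrying these forms is honest comparison with the solver.
* The HPM pair is published in its own scaled variables (`CSP`, `CHP`);
  the published scaling back to $S$ and $H$ is typographically ambiguous,
  so the package keeps the scaled variables and does not guess.
* The HAM control parameter defaults to $h = -1$ (the usual convention)
  and is exposed. At $h = -1/3$ the HAM pair coincides term-by-term with
  the MADM pair — a useful algebraic cross-check that the tests assert.

All three series are quadratics in $R$ built to satisfy the boundary
conditions identically; they agree with the solver only to first order in
$a = \gamma_E/(1+\alpha)$, because the true $O(a)$ correction contains a
$1/R$ term no quadratic can represent. They are therefore trustworthy only
for $a \ll 1$, and the package treats the solver, not the series, as the
reference everywhere. For the stiff default cases (e.g.
$\alpha = 100, \gamma_E = 30$, where $a \approx 0.3$ and the depletion is
severe) the series' interior values are qualitatively wrong — the
comparison table makes this visible rather than hiding it.

## The surrogate

`mlp_init()` builds a 1-$H$-1 perceptron: one radial input mapped affinely
to $[-1, 1]$, $H$ log-sigmoid hidden units
($f(x) = 1/(1+e^{-x})$), and a linear output. The reference experiments
use $H = 60$ (181 trainable parameters). Hidden weights follow the
Nguyen-Widrow scheme (magnitude $0.7H$, random signs, biases spread
linearly across the active range); the output layer starts small and
random. The output layer is linear and targets are fitted unscaled because
$S, H \in [0, \sim 1]$ already.

`lm_train()` is a from-scratch Levenberg-Marquardt loop on the full
parameter vector: per-point error Jacobian assembled analytically,
proposed step from $(J^\top J + \mu I)\,\delta = J^\top e$, acceptance
(training MSE decreased) scaling $\mu$ by `mu_dec`, rejection by `mu_inc`
with a retry that reuses $J^\top J$. Stopping: gradient infinity-norm
below `grad_tol`, $\mu$ exceeding `mu_max`, the epoch cap, or
`max_val_fail` consecutive epochs of rising validation MSE; the returned
network carries the best-validation weights. Defaults:
$\mu_0 = 10^{-3}$, increase 10, decrease 0.1, $\mu_{max} = 10^{10}$,
`grad_tol` $10^{-7}$, 1000 epochs, 6 validation failures.

Data splitting is a seeded 70/15/15 random partition
(train/validation/test). The 70/15/15 ratio is the only self-consistent
reading of the mixed conventions in circulation for this experiment
family, and the fractions are exposed in `split_dataset()`.

### What the generated data emulate — and what they do not

Training data come from the package's own reference solver on the study
grids (1143 points on $[1, 5]$, 1251 on $[1, 1.5]$), so the targets are
smooth, noise-free, and exactly consistent with the model. Surrogate
validation MSEs of $10^{-13}$–$10^{-11}$ demonstrate that the training
pipeline can drive a 60-unit network to the data's information content;
they say nothing about robustness to measurement noise, model mismatch, or
extrapolation beyond $[1, q]$, none of which the generator emulates. The
stability study (`stability_study()`, default 20 seeded runs) measures
sensitivity to the random split and initialization only.

## Fit metrics

`fit_metrics()` reports MSE, mean absolute deviation, Theil's inequality
coefficient
$\mathrm{TIC} = \sqrt{\tfrac1N\sum e_m^2} \big/
(\sqrt{\tfrac1N\sum y_m^2} + \sqrt{\tfrac1N\sum \hat y_m^2})$,
Nash-Sutcliffe efficiency, $\mathrm{ENSE} = 1 - \mathrm{NSE}$, and the
Pearson correlation. The NSE denominator is centred, by default, on the
mean of the *predictions* — the form this experiment family prints —
rather than the conventional observation mean; the conventional form is
available via `nse_form = "observation-mean"`. Zero denominators (constant
series) yield `NaN`, never a silent 0. Histogram bins
(`error_histogram()`) are uniform and right-open with the final bin
closed.

## Scenario defaults

`default_scenarios()` fixes the study conditions: scenario I with
$q = 5$ and 1143-point datasets, scenario II with $q = 1.5$ and 1251
points, each with cases $(\alpha, \gamma_E) = (100, 30), (50, 20),
(10, 10)$. Two interpretive choices are baked in: the radial domain is
$[1, q]$ (the only reading compatible with the boundary conditions, even
though dataset ranges are sometimes quoted from 0), and
$\gamma_S = \gamma_E$ per case (equal diffusivities $D_H = D_S$; no
separate $\gamma_S$ is published for these cases). Both are plain fields
of `scenario_spec()` and can be overridden.

## Problem sizes used by the tests

Unit tests run the solver mostly at $n = 201$–$1001$ and the full
reference checks at $n = 4001$; training tests use 10–60 hidden units on
201–1143 points; the stability studies use the full 20-run, 60-unit,
1143-point configuration. These are the package's reference conditions,
chosen to match the study design while keeping a complete test run in the
low minutes on one core.

## Known limitations

* Steady state only; no transient solver.
* No electrode-current conversion: the amperometric signal requires an
  electrode model that is not part of this package's scope.
* The closed-form series are carried as published benchmarks, not as
  usable approximations outside $\gamma_E/(1+\alpha) \ll 1$.
* The surrogate interpolates one scalar profile per network; it is not a
  parametric emulator over $(\gamma_E, \gamma_S, \alpha, q)$.
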