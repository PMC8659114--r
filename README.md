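# microdisk

Steady-state reaction–diffusion modelling of an enzyme-film **micro-disk
biosensor** with Michaelis–Menten kinetics, for electro-analytical
chemists and modellers who need reference concentration profiles, honest
evaluations of published closed-form approximations, and a reproducible
neural-network surrogate pipeline.

## The model

The electrode is a hemisphere of radius $r_0$ coated by an enzyme film out
to $r_1$. At steady state the dimensionless substrate $S(R)$ and hydrogen
peroxide $H(R)$ on $R \in [1, q]$, $q = r_1/r_0$, satisfy

$$S'' + \frac{2}{R}S' - \frac{\gamma_E S}{1+\alpha S} = 0, \qquad
H'' + \frac{2}{R}H' + \frac{\gamma_S S}{1+\alpha S} = 0,$$

with $S'(1)=0$, $H(1)=0$, $S(q)=1$, $H(q)=0$. Here $\gamma_E, \gamma_S$
are Thiele-modulus-like reaction–diffusion parameters and
$\alpha = C_S^*/K_M$ is the saturation parameter.

The package provides:

* `solve_profile()` — damped-Newton finite-difference reference solver
  (second order, verified against exact first-order and saturated limits);
* `reconstruct_peroxide_harmonic()` / `harmonic_invariant_residual()` —
  the identity that $\gamma_S S + \gamma_E H$ is harmonic ($a + b/R$),
  used as an independent route to $H$ and as a consistency diagnostic;
* `madm_profiles()`, `ham_profiles()`, `hpm_profiles()`,
  `saturated_limit_profile()` — published closed-form approximations,
  evaluated exactly as printed with validity reported;
* `mlp_init()` / `lm_train()` — a from-scratch 1–60–1 log-sigmoid MLP
  surrogate trained by Levenberg–Marquardt with validation early stopping;
* `fit_metrics()`, `stability_study()` — MSE / MAD / Theil's inequality
  coefficient / Nash–Sutcliffe efficiency and 20-run stability summaries;
* `run_scenario()`, `comparison_table()` and a thin CLI
  (`inst/cli/microdisk.R`) orchestrating the reference scenarios
  ($q = 5$ with 1143-point datasets; $q = 1.5$ with 1251).

## Worked example

```r
library(microdisk)

p    <- model_params(gamma_E = 10, gamma_S = 10, alpha = 10, q = 5)
prof <- solve_profile(p, solver_options(n = 1143))
prof
#> concentration profile (numerical), 1143 points on [1, 5], components: S, H
#>   S(1) = 0.000312912, S(q) = 1
#>   max H = 0.80454

dat <- generate_dataset(p, 1143)
ds  <- split_dataset(dat$S, seed = 1)          # 70/15/15 train/val/test
fit <- lm_train(mlp_init(60, q = 5, seed = 1), ds)
fit$record
#> LM training: 12 epochs, stop = grad_tol
#>   best val MSE = 3.315e-10, final train MSE = 2.358e-11
#>   final gradient = 7.839e-08, final mu = 1.000e-06

fit_metrics(ds$target, mlp_forward(fit$net, ds$R))
#> fit metrics: MSE = 8.6253e-11, MAD = 1.4798e-06, TIC = 1.4325e-05, NSE = 1.000000, ENSE = 1.2076e-09, r = 1.000000
```

Reading the numbers: at $\gamma_E = 10, \alpha = 10$ the film nearly
depletes the substrate at the electrode ($S(1) \approx 3 \times 10^{-4}$)
while peroxide accumulates mid-film (max $H \approx 0.80$). The 60-unit
surrogate interpolates the solved profile to validation MSE
$\sim 3 \times 10^{-10}$ — absolute errors around $10^{-6}$ — and its
predictions correlate with the reference at $r = 1.000000$.

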