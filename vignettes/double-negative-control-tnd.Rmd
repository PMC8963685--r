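---
title: "Estimating vaccine effectiveness from test-negative designs with double negative controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vaccine effectiveness from test-negative designs with double negative controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tndnc)
```

## The problem

A test-negative design (TND) recruits symptomatic individuals who seek care
and are tested for the infection under study: test-positives become cases,
test-negatives controls, and vaccine effectiveness (VE) is read off the
vaccination contrast between them. Selection into the sample is therefore
outcome-dependent, and it is also driven by latent traits — health-care
seeking behaviour, occupation, prior infection — that influence vaccination
and infection risk. Conditioning on being tested opens a collider path
between vaccination `A` and infection `Y` through these latent traits `U`,
on top of ordinary confounding by `U`. The conventional logistic regression
of test result on vaccination (plus measured covariates `X`) is biased under
either mechanism.

`tndnc` implements a proximal-inference estimator that corrects both biases
using two auxiliary *negative control* measurements that the analyst
declares a priori:

* a **negative control exposure** `Z` (e.g. prior-season or unrelated
  vaccination) with no causal effect on `Y` or on selection, associated with
  them only through `U`;
* a **negative control outcome** `W` (e.g. unrelated acute-care visits) that
  is not caused by `A` or `Z` and is associated with them only through `U`.

## Model and estimator

The target is the causal risk ratio `RR = E[Y(1)] / E[Y(0)]`, with
`beta0 = log RR` and `VE = 1 - exp(beta0)`. Three structural assumptions
drive identification: selection is treatment-independent given
`(Y, U, W-type triggers, X)`; the vaccine effect is constant on the RR scale
across `(U, X)` strata; and infection is rare within strata. The key device
is a *treatment confounding bridge function* `q(A, Z, X)` satisfying

    E[ q(a, Z, X) | A = a, U, X ] = 1 / P(A = a | U, X),

i.e. a function of observables whose conditional mean reproduces the inverse
treatment probability that we cannot compute because `U` is unobserved.
Given any such `q`, the weighted case contrast

    beta_hat = log( sum_i q_i A_i Y_i / sum_i q_i (1 - A_i) Y_i )

is consistent for `beta0` in the selected sample. The bridge itself is
estimated from the *test-negative controls only*, by solving the moment
equations

    (1/n) sum_i (1 - Y_i) [ m(W_i, A_i, X_i) q(A_i, Z_i, X_i; tau)
                            - m(W_i, 1, X_i) - m(W_i, 0, X_i) ] = 0

for a user-chosen `m` with `dim(m) >= dim(tau)`. Under the rare-infection
condition the control subsample stands in for the target population; under
the exact null of no vaccine effect the substitution is exact at any
prevalence, so the procedure remains a valid test of the null for common
infections. When vaccination itself influences care-seeking the identical
computation retains validity on the odds-ratio scale (recorded via
`scale = "OR"`); no separate algorithm is needed.

Two bridge families are built in:

* `"saturated"` — `tau0 + tau_z Z + tau_a A + tau_za Z A` for binary
  negative controls, with `m = (1, W, A, W A)`; algebraically identical to
  solving the 2x2 control-cell linear system (`closed_form_binary_bridge()`);
* `"logistic"` — `1 + exp((-1)^A (tau0 + tau1 A + tau2' Z + tau3' X))`, the
  exact bridge implied by a logistic treatment model with Gaussian NCE, with
  `m = (1, W, A, X)`.

Joint inference for `(beta, tau)` stacks the estimating functions and uses
the M-estimation sandwich `(O'O)^-1 O' Var(G) O (O'O)^-1 / n`, whose
projection form also covers over-identified moment sets. VE intervals
transform the Wald limits for `beta` endpoint-by-endpoint (not by a delta
method on the VE scale), which keeps them inside `(-Inf, 1)` and preserves
the monotone `beta -> VE` ordering.

With `effect_modifiers`, `beta0(X) = d(X)'b` with `d(X) = (1, X_mod)` and
`b` solves the `d(X)`-weighted vector version of the case contrast by
Newton iteration — the minimal vector extension consistent with the
identification argument. Inference widens the `beta` block accordingly.

```{r example, eval = FALSE}
pop <- simulate_population(dgp_preset("binary-rare", beta0 = -0.693), seed = 7)
fit <- estimate_ve(select_tnd_sample(pop))
glance(fit)
tidy(fit, components = "all")
```

## What the generators emulate

Two synthetic settings expose the full latent structure (`u`, `d`, `s`) so
that oracle quantities exist:

* **binary**: binary `U`, `Z`, `W`, a log-linear risk model
  `Y | A, U ~ Bern(exp(eta0y + beta0 A + etauy U))`, an auxiliary flu-like
  illness `D`, and selection that can only trigger when `Y`, `W` or `D` is
  one;
* **continuous**: standard-normal `U`, `X`; logistic treatment; Gaussian
  `Z` and `W`; log-linear risk with a `U x X` interaction; selection through
  `Y` or `D`.

Selection depends only on `(Y, W, D)`, so treatment-independent sampling
holds by construction; the generator never leaks `u`, `d` or `s` into the
analytic sample.

### Calibration of the defaults

The defaults are fixed study conditions, not tuning knobs:

* unvaccinated prevalence is 0.75% (binary) and 0.34% (continuous); the
  outcome intercepts are solved analytically (binary) or by Gauss-Hermite
  quadrature (continuous) to hit these targets exactly;
* the marginal confounding ratio `E[g(U)|A=1]/E[g(U)|A=0]` is 1.25 in the
  binary setting; together with ~36% vaccination coverage this reproduces
  overall infection prevalences of about 0.55/0.65/0.72% as `beta0` runs
  through log(0.2)/log(0.5)/log(0.7). A much stronger confounding ratio
  would be incompatible with the per-arm prevalence pattern above, because
  under the log-linear risk model the vaccinated-arm prevalence must scale
  exactly as `exp(beta0)` across scenarios;
* negative controls are informative proxies
  (`P(Z=1|U) = 0.10/0.85`, `P(W=1|U) = 0.10/0.70`). This matters
  numerically: the control-sample cell system that identifies the bridge
  has condition number ~6 under these defaults, against ~19 for weak
  proxies (e.g. `0.2/0.7`), at which point bridge estimates at realistic
  TND sizes become unstable and the weighted case sums can degenerate;
* selection probabilities (`0.15` for cases, `0.024` for `W`/`D`-triggered
  controls) give samples of roughly 8-9 thousand per million population,
  with a control pool large enough that bridge-estimation noise does not
  dominate the estimator;
* the `"binary-nonrare"` preset raises the unvaccinated prevalence to 10%
  to probe the rare-infection approximation: the control-estimated bridge
  then acquires bias of order `prevalence x (1 - RR)` except under the
  null, while the oracle bridge stays unbiased. The asymptotic size of this
  bias (about -0.05 at `beta0 = log 0.5`) was verified by exact enumeration
  of the discrete population.

What the generators deliberately do not emulate: interference or household
transmission, test misclassification, time-varying vaccination status, and
real covariate structure (one scalar `X` at most). Passing the simulation
suite shows the estimator does what the theory promises under its stated
assumptions — not that those assumptions hold in any particular EHR or
surveillance dataset.

## Numerical choices

* **Solving the moment equations.** Just-identified systems are solved by
  damped Newton iteration with central-difference Jacobians (step
  `1e-6 (1 + |tau|)`), tolerance `1e-10` on the residual max-norm, at most
  200 iterations, and eight deterministic quasi-random restarts (golden-angle
  perturbations) on failure. Over-identified systems minimise the
  identity-weighted quadratic form by Gauss-Newton; optimal GMM weighting is
  deliberately not used so that the variance formula keeps the same
  projection form as the reported sandwich. Saturated-family systems are
  linear in `tau` and converge in one step.
* **Starting values.** `q == 1` (saturated); for the logistic family, the
  no-residual-confounding solution `1 / P(A = a | Z, X)` from a logistic
  regression among controls. With noisy small control samples the
  exp-family system occasionally has no root (the data demand bridge values
  below 1, which the family cannot produce); this is reported as a
  convergence error rather than silently returning a stationary point, and
  the study driver counts such replicates as failures.
* **Validity flag.** Fitted saturated bridges may take values below 1 even
  though an inverse probability cannot; values below 1 trigger a warning
  with the offending fraction. No truncation is applied by default
  (`floor_at_one = FALSE`), since the estimating equations, not the
  pointwise values, carry the identification.
* **Closed-form cell solver.** The 2x2 system is declared unidentified when
  its condition number exceeds `1e8` — the NCE then carries essentially no
  information about the conditioning variable.
* **Degenerate samples.** No vaccinated (or unvaccinated) cases aborts with
  a message naming the empty arm rather than returning infinite estimates.
* **Seeds.** All randomness flows from one seed; Monte Carlo drivers derive
  per-replicate seeds by a single upfront `sample.int()` stream split.

## Design choices where the method leaves room

* **Moment basis.** The default `m` follows the two families above;
  applications with several negative controls or covariates may reasonably
  include more two-way interactions, and `moment_spec()` accepts any basis
  of sufficient dimension. Over-identified bases are projected, not
  reweighted (see above).
* **Effect modification.** `d(X) = (1, X_mod)` is the minimal design; any
  richer basis would need its own positivity diagnostics.
* **Hausman comparison.** `hausman_test()` uses the classical scalar form
  `(b1 - b2)^2 / (V1 - V2)` with one degree of freedom, returning `NA` with
  a warning when the variance ordering fails. Covariance-adjusted variants
  exist; the simple form is reported because both inputs here are scalar
  summaries of separately fitted models.
* **Study sizes.** The bundled Monte Carlo experiments use populations of
  one million with 300 replicates (200 for the non-rare variant) — large
  enough that empirical bias bounds of twice the Monte Carlo standard error
  are meaningful, while a full bias/coverage sweep completes in minutes on
  a single core.

## Known limitations

* The rare-infection approximation leaves an intrinsic asymptotic bias of
  order `prevalence x (1 - RR)` in the control-estimated bridge; it is
  negligible at sub-percent prevalences but visible at 10% (the non-rare
  preset exists to show exactly this).
* Bridge estimation needs genuinely informative negative controls; with
  weak proxies the cell system is ill-conditioned and estimates are
  unstable. `nce_bias_tests()` helps assess whether the negative controls
  are associated with anything at all, but cannot certify their validity.
* Only parametric bridge families are provided; nonparametric or sieve
  estimation, optimal GMM weighting, and doubly robust outcome-bridge
  estimators are out of scope.
* The saturated family assumes binary `Z` (componentwise); polytomous NCEs
  would need a richer basis.
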