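---
title: "Population pharmacokinetics of dual-absorption oral drugs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of dual-absorption oral drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pkdual` analyses single-oral-dose plasma concentration studies whose
profiles show a secondary peak, the pattern seen with enterohepatic
recycling or staged gastrointestinal release — for example meloxicam given
orally to dogs, where a free solution can be compared with a
nanoencapsulated formulation. This vignette is the package's account of the
models it implements, the numerical choices behind them, and what its tests
do and do not demonstrate.

## The structural model

Plasma concentration follows a two-compartment disposition with linear
elimination, fed by **two parallel first-order absorption paths**. A
fraction $F_1$ of the absorbed dose enters through path 1 at rate $k_{a1}$
starting at the dose time; the remainder $1 - F_1$ enters through path 2 at
rate $k_{a2}$, delayed by a lag time $T_{lag2}$. The lag applies only to
the second path: it is the delayed, faster path that produces the second
peak, phenomenologically capturing gastrointestinal recycling without
modelling its mechanism.

With micro-constants $k_{10} = CL/V_1$, $k_{12} = Q/V_1$, $k_{21} = Q/V_2$
and hybrid macro-constants $\lambda_{1,2}$ (the roots of
$s^2 - (k_{10}+k_{12}+k_{21})s + k_{10}k_{21}$), each path contributes the
standard bi-exponential oral solution shifted by its start time, and the
total concentration is their sum. `predict_concentration()` evaluates this
closed form; `predict_concentration_ode()` integrates the four-state system
with `deSolve` and ships permanently as an independent cross-check (the two
agree to better than $10^{-5}$ relative over wide random parameter ranges —
see the test suite). When an absorption rate collides with a disposition
root the closed form has a removable singularity; inside a relative window
of $10^{-8}$ the kernel switches to the analytic limit (terms in
$t\,e^{-\lambda t}$), so no parameter combination produces `NaN`.

Two numerical conventions deserve note. First, $\lambda_2$ is computed from
the product identity $\lambda_1\lambda_2 = k_{10}k_{21}$ rather than the
subtractive quadratic root, avoiding cancellation when the roots are far
apart. Second, oracle comparisons against the ODE integrator exclude points
below $10^{-6}\times C_{max}$: an absolute-tolerance integrator cannot
resolve deep exponential tails, and discrepancies there reflect integrator
error, not model error.

**Units** are canonical throughout: time h, concentration µg/mL (≡ mg/L),
dose mg/kg, volumes L/kg, clearances L/h/kg. Because doses are per kg and
volumes per kg, body weight cancels; weight is retained in datasets only as
a candidate covariate. Clearance can be reported in the mL/min/kg
convention (multiply by 1000/60). All oral-data parameters are apparent
(CL/F, V/F): absolute bioavailability is not identifiable from oral data
alone and is treated as 1 inside the model.

## The hierarchical (population) model

Individual parameters are lognormal around covariate-adjusted typical
values,

$$P_i = P_{pop}\, e^{\beta x_i}\, e^{\eta_i}, \qquad \eta_i \sim
N(0, \omega_P^2),$$

independently per parameter. The absorbed fraction is the exception: $F_1$
lives on the logit scale ($\mathrm{logit}\,F_{1,i} =
\mathrm{logit}\,F_{1,pop} + \eta_i$), so realized values stay inside
$(0,1)$; an exponential model with $\omega_{F1} = 0.67$ would routinely
exceed 1. The same convention is used by the simulator and the estimator,
so recovery studies are internally consistent.

Covariates are multiplicative-exponential: for the formulation factor,
$x_i$ is the indicator of the nanocapsule arm, so the NC-arm typical value
is $P_{pop}e^{\beta}$; continuous covariates (weight, age) use
$x_i = \log(\mathrm{cov}_i/\mathrm{ref})$, i.e. power models normalised at
the data median. In the reference model the formulation acts on $T_{lag2}$
($\beta = 0.74$: 1.22 h → 2.55 h) and on $V_2$ ($\beta = 1.11$: 0.134 →
0.406 L/kg).

Residual error is proportional, $y_{ij} = f_{ij}(1 + b\,\varepsilon_{ij})$
with $\varepsilon \sim N(0,1)$, so the measurement SD scales with the
concentration; additive and combined models are available for error-model
comparison but the reference analysis is proportional. All parameters
except $Q$ carry IIV; $\omega_Q = 0$ reflects that the intercompartmental
clearance of a sparse oral design is too weakly informed to support a
random effect.

## Estimation: SAEM

`fit_saem()` maximises the marginal likelihood by stochastic approximation
EM. Design choices, in the order they matter:

* **E-step.** Componentwise Metropolis-within-Gibbs on each subject's
  transformed parameters: a random-walk kernel whose scale adapts during
  exploration toward ~35% acceptance, followed by an independence kernel
  drawing from the current population distribution (cheap jumps out of
  local modes). Both run in compiled code; `n_kernel` sweeps per iteration
  (default 2).
* **Schedule.** $K_1 = 500$ exploration iterations with step size 1, then
  $K_2 = 200$ smoothing iterations with step $1/(k-K_1)^{0.7}$. The
  defaults were sized on studies of 18–200 subjects; the convergence flag
  compares the trace's relative drift over the final smoothing stretch.
* **M-step.** Typical values and covariate coefficients are linear-Gaussian
  in the sampled log-parameters, so they update in closed form from
  stochastically-averaged sufficient statistics; $\omega^2$ likewise.
  Parameters without IIV (here $Q$) are non-conjugate and take one damped
  Newton step per iteration on the complete-data likelihood. The
  proportional-error coefficient has the closed-form update
  $b^2 = \frac1N\sum((y-f)/f)^2$.
* **Stabilisers.** Three safeguards address the pathologies we observed on
  small studies. (1) *Simulated annealing*: during exploration each
  $\omega^2$ (and $b^2$) may shrink by at most 5% per iteration, preventing
  early collapse of under-sampled variabilities. (2) *Plausibility bounds*
  on typical values (e.g. absorption rates ≤ 50 h⁻¹, central volume ≥
  1 mL/kg): the likelihood is flat in directions like $k_{a2} \to \infty$
  (an absorption faster than the first sampling time is indistinguishable
  from a bolus), and an unbounded random walk drifts along such ridges.
  (3) An $\omega$ floor of $10^{-4}$ (with warning) and cap of 3.
* **Starting values** default to crude NCA-informed guesses (clearance from
  mean exposure, mid-range values elsewhere); recovery tests deliberately
  start away from the truth.
* **Degenerate-IIV polish.** When every estimated $\omega$ ends below 0.05
  the model is effectively fixed-effects, and the stochastic
  approximation's station noise (a percent or two) exceeds the statistical
  uncertainty; the fit then finishes with a direct BFGS maximisation of
  the fixed-effect likelihood over the typical values and the error
  coefficient. Even so, recovery of $V_1$ and $Q$ from near-noiseless data
  requires samples inside the distribution phase (minutes after dosing):
  without them the likelihood is a few OFV units wide across 10–15%
  changes in those parameters, and no optimizer can do better than the
  data allow.

The marginal $-2\log L$ is computed by importance sampling around each
subject's conditional distribution (moments taken from the smoothing-phase
MCMC), using a multivariate $t(4)$ proposal — a normal proposal produced
occasional unbounded weights and multi-unit drift in the estimate. A
Laplace approximation is available as a deterministic alternative.
Relative standard errors come from a linearized (first-order) Fisher
information: per subject the marginal covariance is
$B_i\,\Omega\,B_i' + R_i$ with $B_i = \partial f/\partial\eta$ at
$\eta = 0$, differentiated numerically over all estimated parameters.
Empirical Bayes estimates are per-subject conditional modes (BFGS), from
which $\eta$-shrinkage is $100(1 - SD(\eta_{EBE})/\omega)$.

## Covariate search

`covariate_search()` implements forward inclusion / backward elimination on
the objective function: a candidate enters when its inclusion drops
$-2\log L$ by more than 3.84 (the 5% $\chi^2_1$ point) and survives when
its removal costs more than 6.63 (the 1% point). All fits share one seed so
Monte-Carlo errors are positively correlated across nested models, and
fits are cached by covariate-set. The OFV noise budget matters here: with
the default schedule and `ll_nsim = 3000` the between-fit SD of the OFV is
roughly one unit, comfortably below the thresholds; materially shorter
schedules let noise masquerade as covariate effects.

The package's selection-consistency experiment uses 25 dogs per arm. That
size is a power calculation, not a tuning knob: the weaker true effect
($\beta_{V2} = 1.11$ against $\omega_{V2} = 0.65$) needs
$n \gtrsim 2(z_{0.975}+z_{0.95})^2(\omega/\beta)^2 \approx 9$ per arm in an
idealised two-sample test, and sparse-design EBE noise inflates the
effective variance several-fold; 25/arm buys ~95% joint power for both
effects. The 9-per-arm reference design is kept for the type-I
(false-inclusion) replicates, where power is irrelevant.

## Non-compartmental analysis

`nca_single()` computes the standard single-dose metrics. The terminal
slope uses log-linear least squares over contiguous terminal subsets of 3–6
points strictly after $T_{max}$, picking the best adjusted $R^2$ (ties go
to more points) — the common automatic rule in NCA software. AUC uses the
linear trapezoid with a zero origin point (a log-down variant is available
behind a flag). Derived quantities are exact identities:
$t_{1/2} = \ln 2/\lambda_z$, $CL/F = \mathrm{dose}/AUC_{0-\infty}$,
$V_d/F = (CL/F)/\lambda_z$, MRT from AUMC with the analytic tail. The
group comparison uses Welch's $t$-test by default (the pooled-variance test
is a flag); relative bioavailability is the ratio of mean $AUC_{0-\infty}$,
and absolute bioavailability requires a user-supplied intravenous reference
exposure — it is never hard-coded.

Under the reference generating parameters some simulated dogs peak at 36 h
or later, leaving fewer than three terminal points; `nca_dataset()` can
either fail loudly or flag-and-omit such subjects (`on_error = "omit"`),
mirroring how NCA software reports non-estimable profiles.

## Diagnostics

* **VPC** (`vpc()`): since every subject shares the design schedule, bins
  are the exact nominal times; observed 10th/50th/90th percentiles are
  compared with the envelope of the same percentiles across simulated
  replicate studies (90% prediction band by default, matching the common
  presentation).
* **NPDE** (`npde()`): simulation-based residuals, decorrelated per subject
  with the simulated mean and covariance (Cholesky), rank-transformed
  through the inverse normal. Approximately $N(0,1)$ under a correct
  model; singular simulated covariances are jittered with a warning.
* **Bootstrap** (`bootstrap_pk()`): nonparametric, resampling subjects with
  replacement *within* each formulation arm so the two-arm balance is
  preserved. Replicate refits start at the supplied estimates with a
  shortened schedule (default 200/100), which the result records. Medians
  and 5th/95th percentiles are reported per parameter.
* **External validation** (`external_validate()`): predictions with the
  population parameters held fixed (covariates applied, $\eta = 0$, no
  refitting) against any user-supplied dataset of observed profiles, scored
  by $MPE\% = \frac{100}{N}\sum\frac{C_{pred}-C_{obs}}{C_{obs}}$ and the
  root-mean-square relative error $RMSE\% =
  100\sqrt{\frac1N\sum\left(\frac{C_{pred}-C_{obs}}{C_{obs}}\right)^2}$.
  The square root is taken over the mean squared *relative* error, so
  RMSE ≥ |MPE| always, and both are invariant to joint unit rescaling.

## The virtual dog study

`simulate_study()` is the package's standing replacement for raw study
data: 9 dogs per arm, one 0.2 mg/kg oral dose, plasma samples at 0.5, 1, 2,
4, 6, 8, 12, 24, 36, 48, 60 h, weights uniform on 10.5–16.6 kg, ages 9–48
months, individual parameters drawn from the reference hierarchical model
and observations perturbed with proportional noise ($b = 0.19$). Negative
draws — possible under Gaussian proportional noise at this $b$ — have their
$\varepsilon$ redrawn, keeping every observation positive (all values above
the quantification limit, as in the study the defaults emulate); the policy
is configurable. The realized individual parameters are attached to the
dataset for recovery experiments. `simulate_external_means()` produces
population-typical mean profiles per arm, optionally distorted by a
constant relative bias or proportional noise, sized to mimic small external
literature pools (e.g. 28- or 66-point sets).

What the generator does *not* emulate: missing samples (the emulated study
reports 196 of a possible 198 observations; the generator produces all
198), assay error structure beyond proportional Gaussian noise,
below-quantification censoring, covariate effects of weight/age (simulated
but inert, to exercise the search's null behaviour), and any
surgery-related time-varying physiology. Passing recovery tests therefore
demonstrates the estimator against its own assumptions, not against real
dogs.

## Problem sizes used by the test suite

The tests balance statistical resolution against a single-CPU budget:
parameter recovery uses 100 dogs/arm (tolerances scaled to the reference
RSEs); selection consistency 20 replicates at 25 dogs/arm; type-I control
50 replicates of the 9/arm design; NPDE/VPC calibration ~550 observations
with 300–500 simulated replicates; the bootstrap demonstration 200
replicates of a 30-dog study with a shortened refit schedule. The
full-sized analyses (1000 VPC simulations, 1000 bootstrap replicates) are
one-argument changes.

## Known limitations

* Single oral dose only: no multiple dosing, infusions, or IV records.
* No eta correlations (none are reported for the reference model) and no
  between-occasion variability.
* The RSE machinery is a first-order linearization; it inherits that
  approximation's optimism for highly nonlinear parameters ($k_{a2}$,
  $V_1$).
* $k_{a2}$ and $V_1$ are weakly identified at study sizes under ~40
  subjects; expect wide bootstrap intervals and occasional boundary-bound
  estimates there (the reference analysis's own bootstrap shows the same
  pattern).
* The absolute OFV is Monte-Carlo approximated; only OFV *differences* at
  matched seeds should be interpreted.
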