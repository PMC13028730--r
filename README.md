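# pkdual

Population pharmacokinetics of orally dosed drugs with **dual first-order
absorption** — the profile shape, with a secondary concentration peak, seen
when part of a dose is absorbed after a delay (staged gastrointestinal
release, enterohepatic recycling). The package grew around a concrete
problem in veterinary pharmacology: comparing meloxicam given to dogs as a
free solution versus a polymeric-nanocapsule formulation in a two-arm,
single-dose (0.2 mg/kg) study, and quantifying how the nanoformulation
changes absorption and distribution. Everything runs on simulated "virtual
dog studies" with the same design, so methods can be exercised and
validated end to end without animal data.

## The model

Plasma concentration follows a two-compartment disposition (volumes
$V_1, V_2$, clearances $CL, Q$, all apparent and per kg) fed by two
parallel first-order absorption paths: a fraction $F_1$ of the dose at rate
$k_{a1}$ from the dose time, and $1-F_1$ at rate $k_{a2}$ after a lag
$T_{lag2}$. Individual parameters are lognormal around covariate-adjusted
typical values,

$$P_i = P_{pop}\,e^{\beta x_i}\,e^{\eta_i},\qquad \eta_i\sim N(0,\omega^2),$$

with the formulation indicator as the covariate of record (on $T_{lag2}$
and $V_2$ in the reference model), $F_1$ handled on the logit scale, and
proportional residual error $y = f(1+b\varepsilon)$. Estimation is
maximum likelihood by **SAEM** (stochastic approximation EM) with a
Metropolis-within-Gibbs E-step in compiled code; model evaluation includes
importance-sampled $-2\log L$/AIC, linearized relative standard errors,
empirical-Bayes shrinkage, visual predictive checks, normalized prediction
distribution errors, stratified nonparametric bootstrap, and the external
validation metrics $MPE\%$ and $RMSE\%$. Non-compartmental analysis
(AUC, $C_{max}$, $T_{max}$, $\lambda_z$, $t_{1/2}$, CL/F, Vd/F, MRT) with a
between-arm Welch test is included for the model-free view of the same
data.

See the vignette `vignettes/dual-absorption-poppk.Rmd` for the full
methods account.

## Worked example

```r
library(pkdual)

# the reference virtual study: 9 dogs/arm, 0.2 mg/kg oral, samples at
# 0.5 ... 60 h, individual parameters from the reference population model
study <- simulate_study(sim_config(), seed = 42)
summary(study)
#> PK study: 18 subjects (9 FREE, 9 NC), 198 observations
#> dose: 0.2 mg/kg
#> weight: 11.2 - 16.5 kg;  age: 9 - 48 months

# model-free exposure metrics and arm comparison (subjects whose terminal
# slope is not estimable are flagged and omitted, as NCA software does)
nca <- nca_dataset(study, on_error = "omit")
cmp <- group_compare(nca)
cmp$table[cmp$table$metric == "cmax", ]
#>   metric  mean_ref    sd_ref mean_test    sd_test    p_value
#> 4   cmax 0.8683571 0.4032764 0.4211779 0.06534302 0.02589968
```

The nanocapsule arm's lower, flatter peak (mean $C_{max}$ 0.42 vs 0.87
µg/mL, p = 0.026) is the model-free signature of the delayed second
absorption path. Population fits resolve it into parameters; here on a
better-powered virtual study (30 dogs/arm):

```r
study2 <- simulate_study(sim_config(n_per_arm = 30), seed = 42)
fit <- fit_saem(study2,
                covariates = data.frame(param = c("tlag2", "V2"),
                                        covariate = "FORM"),
                seed = 1)
fit$model$theta[c("ka1", "tlag2", "CL", "V2")]
#>         ka1       tlag2          CL          V2
#> 0.098480322 1.396588375 0.005862837 0.150071501
fit$model$beta
#>   param covariate     value
#> 1 tlag2      FORM 0.6153401
#> 2    V2      FORM 1.0769881
fit$model$b
#> [1] 0.1943449
```

Read: the typical lag of the second absorption path is 1.40 h for the free
formulation and $1.40\,e^{0.615} = 2.58$ h for the nanocapsules; the
peripheral volume grows by a factor $e^{1.08} \approx 2.9$; the
proportional residual error is 19% (generated: 1.22 h, $\beta = 0.74$ and
$1.11$, $b = 0.19$). The fast-path rate $k_{a2}$ is the model's weakly
identified corner at this study size — expect wide intervals there, as the
bootstrap (`bootstrap_pk()`) makes explicit.

```r
ext <- simulate_external_means(sim_config())  # noise-free mean profiles
unlist(external_validate(fit, ext)[c("mpe_pct", "rmse_pct")])
#>  mpe_pct rmse_pct
#> 4.531875 7.630318
```

Fixed-parameter predictions of external mean profiles land within a few
percent — the same style of check (MPE%, RMSE%) used to validate such
models against literature data.

`run_pipeline(out_dir, seed)` scripts the whole chain — simulate, NCA,
fit, VPC, bootstrap, external metrics — into CSV/JSON artifacts with a
hash manifest; rerunning with the same seed reproduces every file exactly.

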