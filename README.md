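# pocure: cure-fraction survival analysis with jackknife pseudo-observations

Long-term follow-up of cancer trials and other clinical cohorts often shows a
Kaplan–Meier curve that flattens at a positive plateau: a fraction of the
population is *cured* and will never experience the event. Standard cure-model
software estimates such models by EM-type maximum likelihood. `pocure` instead
turns nonparametric estimates of the cure-model quantities into leave-one-out
**jackknife pseudo-observations**,

&nbsp;&nbsp;&nbsp;&nbsp;*ϱ̂ᵢ = n ϱ̂ − (n − 1) ϱ̂⁻ⁱ*,

and treats them as complete-data responses in generalized linear models fitted
by **generalized estimating equations (GEE)**. This gives direct,
likelihood-free regression estimates for both families of cure models:

- **Mixture cure (PHMC)**: S(t) = (1 − π) + π Sᵤ(t), with logistic
  *incidence* logit P(uncured | X) = α₀ + αᵀX and Cox proportional-hazards
  *latency* for Sᵤ(t | Z); fitted from pseudo-observations of
  π̂ = 1 − Ŝ_KM(t_max) (or its promotion-time analogue) and of
  Ŝᵤ(t) = {Ŝ_KM(t) − Ŝ_KM(t_max)}/{1 − Ŝ_KM(t_max)} on a grid of
  event-time quantiles, using logit and complementary log-log links.
- **Bounded cumulative hazard / promotion time (PHPH)**:
  S(t) = exp[−θ(X){1 − F̄(t)^η(Z)}] with *long-term* effect
  θ(X) = exp(γ₀ + γᵀX) (cure rate exp{−θ}) and *short-term* effect
  η(Z) = exp(ϕᵀZ); fitted from pseudo-observations of θ̂ and of F̂(t) with
  log and complementary log-log links.

Variances are estimated by an approximate (one-step) leave-one-subject-out
jackknife (a robust sandwich estimator is also computed), and sparse models
are selected by **SCAD-penalized estimating equations** with five-fold
cross-validated tuning on squared pseudo-residuals. Calibrated simulators for
both designs support Monte Carlo study of the estimators.

## Worked example

Simulate a mixture-cure cohort (20% average cure, ~30% censoring) and fit
both components:

```r
library(pocure)

scenario <- phmc_scenario()                       # alpha0 = 2, alpha1 = -1,
scenario$cens_upper <- calibrate_censoring(scenario, seed = 1)
s <- gen_phmc(1000, scenario, seed = 42)

fit <- fit_phmc(s, flavor = "np", H = 10)
print(fit)
```

```
PHMC pseudo-observation fit (np flavor, H = 10)

Incidence (logit link):
          Estimate Std. Error   z value     Pr(>|z|)
alpha0    1.798854  0.1456959 12.346635 5.079192e-35
alpha_X1 -1.020742  0.1878536 -5.433712 5.519354e-08

Latency (cloglog link):
           Estimate Std. Error     z value     Pr(>|z|)
xi_1    -3.07757304 0.16941784 -18.1655783 9.668298e-74
...
xi_10    0.28048266 0.10955924   2.5601004 1.046419e-02
beta_Z1  0.91047712 0.09937505   9.1620291 5.093049e-20
beta_Z2  0.25376665 0.16434317   1.5441265 1.225577e-01
```

The incidence block recovers the true (α₀, α₁) = (2, −1): the treatment-like
covariate lowers the log-odds of being susceptible by about one unit. The
latency block recovers β = (1, 0.5) up to Monte Carlo error; the ten `xi_*`
coefficients estimate log Λ₀(t_h) at the grid times (for this design,
log(t_h/3)). Cure rates per covariate profile, with the model-free
Kaplan–Meier plateau as benchmark:

```r
cure_rate_table(fit, profiles = cbind(X1 = c(0, 1)))
#>   X1 cure_phmc  cure_km
#> 1  0 0.1419907 0.223695
#> 2  1 0.3147271 0.223695
```

Variable selection on a sparse design (here reusing `s`, whose incidence
block has a single covariate):

```r
sel <- cure_select(s, component = "incidence", flavor = "np", nlambda = 15)
which(sel$selected)     # retained covariates; exact zeros elsewhere
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "pocure.R", package = "pocure")` with subcommands
`fit-phmc`, `fit-phph`, `pseudo`, `select` and `simulate`.

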