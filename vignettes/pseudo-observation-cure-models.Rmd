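---
title: "Pseudo-observation methods for cure-fraction survival models"
author: "pocure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-observation methods for cure-fraction survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocure)
```

## The models

With right-censored data $(\tilde T_i, \delta_i, X_i, Z_i)$,
$\tilde T = \min(T, C)$, $\delta = 1\{T \le C\}$, a cured subject has
$T = \infty$ and is always censored. `pocure` estimates two families of
cure models.

**Mixture cure (PHMC).** $S(t) = (1-\pi) + \pi S_u(t)$, where $\pi$ is the
probability of being susceptible and $S_u$ the conditional survival of the
susceptible. The *incidence* follows a logistic model,
$\mathrm{logit}\,\pi(X) = \alpha_0 + \alpha^\top X$, and the *latency* a
Cox model with hazard $\lambda_0(t)\exp(\beta^\top Z)$.

**Bounded cumulative hazard / promotion time (PHPH).**
$S(t) = \exp[-\theta(X)\{1 - \bar F(t)^{\eta(Z)}\}]$ with
$\theta(X) = \exp(\gamma_0 + \gamma^\top X)$ (the *long-term* effect; cure
rate $e^{-\theta}$) and $\eta(Z) = \exp(\phi^\top Z)$ (the *short-term*
effect, no intercept — the per-time intercepts absorb it).

## Nonparametric ingredients

Everything is built from two nonparametric estimators. The Kaplan–Meier
plateau gives $\hat\pi_{KM} = 1 - \hat S_{KM}(t_{max})$, where $t_{max}$ is
the largest **event** time (censored follow-up may extend beyond it), and
$\hat S_u(t) = \{\hat S_{KM}(t) - \hat S_{KM}(t_{max})\}/\{1 - \hat
S_{KM}(t_{max})\}$. At tied times events are processed before censorings.

Alternatively, `theta_np()` estimates the promotion-time quantity
$\theta = \Lambda(\infty)$ by a closed form over the unique event times
$t_{(1)} < \dots < t_{(D)}$, with $M_j$ events at $t_{(j)}$ and $N_j$
censorings in $[t_{(j)}, t_{(j+1)})$ (censorings before $t_{(1)}$ are kept
in the Kaplan–Meier risk sets but excluded from these counts, which start
at the first event):
$$\hat\theta_k = -\log\frac{\sum_{\ell>k} M_\ell + \sum_{\ell\ge k} N_\ell}
{\sum_{\ell\ge k} M_\ell + \sum_{\ell\ge k} N_\ell},\qquad
\hat\theta = \textstyle\sum_k \hat\theta_k,$$
with jumps $\hat J_j = \hat\theta_j/\hat\theta$ defining a proper
distribution $\hat F(t)$. If no censored subject remains at or after
$t_{(D)}$, $\hat\theta_D = \infty$: the sample shows no plateau and the
estimators are degenerate, which `pocure` surfaces as a typed error
(`pocure_no_plateau`) rather than an infinite value — callers who prefer
the boundary interpretation $\hat\pi = 1$ can catch it.

## Pseudo-observations

For any of these functionals $\hat\varrho$, subject $i$'s
pseudo-observation is $\hat\varrho_i = n\hat\varrho -
(n-1)\hat\varrho^{-i}$, the leave-one-out jackknife linearization. Seven
constructors cover $\pi$ (two flavors), $S_u(t)$, $\theta$ (two flavors)
and $F(t)$ (two flavors). Three numerical choices deserve note:

- **No clipping.** Pseudo-observations routinely fall outside $[0,1]$;
  this is expected and is precisely why the GEE below uses an identity
  (Gaussian-type) working variance.
- **Leave-one-out plateau.** Whether $\hat S^{-i}$ should be read at the
  subsample's own largest event time or at the full sample's is a genuine
  ambiguity; `pocure` uses the subsample's own $t_{max}$ (each leave-one-out
  statistic is exactly the statistic of that subsample) and exposes
  `tmax_rule = "full"` for sensitivity checks. The two differ only for
  subjects whose removal changes $t_{max}$.
- **Degenerate subsamples** (for example removing the only event) raise an
  error naming the subject; `on_degenerate = "drop"` instead drops those
  subjects with a warning and the fitters exclude them.

The engine literally refits the statistic on each of the $n$ subsamples.
An incremental update would be faster but error-prone; at the sample sizes
these models are used for (hundreds to a few thousand subjects) the naive
loop costs well under a second per construction, and it keeps the code
identical to its mathematical definition.

## GEE estimation

Each component is a GLM for the pseudo-observation responses:
logit link for incidence, $\log$ for the long-term effect, and the
survival-type complementary log-log $g(x) = \log\{-\log x\}$ for latency
($g\{S_u(t_h|Z)\} = \xi_{t_h} + \beta^\top Z$, $\xi_{t_h} = \log
\Lambda_0(t_h)$) and for the short-term component (responses $1 - \hat
F_i(t_h)$, per-time intercepts $\varsigma_{t_h} = \log\{-\log \bar
F(t_h)\}$). Time-indexed components share slopes across a grid of $H$ time
points with one intercept per grid time.

The grid takes the interior quantile levels $h/(H+1)$, $h = 1, \dots, H$
(type-7 interpolation, default $H = 10$), of the observed event times.
Interior levels avoid the degenerate endpoints: at $t \approx 0$ every
pseudo-observation is 1, and at $t_{max}$ the susceptible survival is 0 by
construction. If fewer than $H$ distinct event times exist, all of them
are used.

Fisher scoring solves $U(\psi) = \sum_i D_i^\top V_i^{-1}(y_i - \mu_i) =
0$ with $V_i = \phi R(\rho)$: **identity variance function** (a
mean-variance relationship would be meaningless for out-of-range
pseudo-observations) with moment-estimated dispersion, and a working
correlation that is independence by default — exchangeable and AR(1) are
available but bring no measurable gain in our simulations, consistent with
the usual experience with pseudo-observation GEEs. Initialization uses the
link of clamped response means for the intercept block and zero slopes;
convergence is declared at a maximum coefficient change below $10^{-8}$
(cap 100 iterations, non-convergence flagged but the fit returned).

**Variances.** The sandwich $A^{-1}BA^{-1}$ is computed alongside an
approximate jackknife: one Newton step from the full-data solution after
deleting cluster $i$ gives $\hat\psi^{(-i)} = \hat\psi - A_{-i}^{-1}
U_i(\hat\psi)$, and
$\widehat{\mathrm{Var}} = \frac{n-k}{n}\sum_i (\hat\psi^{(-i)} -
\bar\psi)(\hat\psi^{(-i)} - \bar\psi)^\top$. The jackknife is the default
reported estimator; for linear estimating equations the one-step deletion
is exact (the suite verifies agreement with full refitting to $10^{-3}$
there), while for nonlinear links it differs from full refitting by a
linearization error of order $1/n$, which is the standard behavior of
approximate-jackknife GEE variances.

**Diagnostics.** Pseudo-residuals $y_{ih} - g^{-1}(\hat\eta_{ih})$ per
subject (and grid time) plot against covariates; a visible trend indicates
a misspecified component.

## SCAD-penalized selection

Each component's estimating function can be penalized,
$S(\psi) = U(\psi) - n\,q_\lambda(|\psi_P|)\circ\mathrm{sign}(\psi_P)$,
with the SCAD derivative $q_\lambda(u) = \lambda 1\{u\le\lambda\} +
(a\lambda-u)_+/(a-1)\,1\{u>\lambda\}$ and $a = 3.7$ (the standard
convention; large coefficients are left unshrunken). Intercepts and
time-dummy blocks are never penalized. The equation is solved by a local
quadratic approximation, iterating
$\psi \leftarrow \psi + (A + nE)^{-1}\{U - nE\psi\}$ with $E_{jj} =
q_\lambda(|\psi_j|)/(\epsilon + |\psi_j|)$, $\epsilon = 10^{-6}$, from the
unpenalized fit (the equations are nonconvex, so a consistent starting
point matters). Coefficients below $10^{-3}$ in magnitude at convergence
become exact zeros and the equation is re-solved on the surviving active
set — a saturating $\lambda$ therefore reproduces the intercept-only fit
exactly, and $\lambda = 0$ the unpenalized GEE.

$\lambda$ is tuned by five-fold cross-validation at the subject level: for
each fold the model is fitted on the complement and scored by the mean
squared pseudo-residual of held-out subjects, averaged over folds; the
minimizing $\lambda$ is refitted on all data. The grid is 30 log-spaced
values from the saturating $\lambda_{max}$ (found by doubling search) down
to $0.01\lambda_{max}$; the grid, the LQA constants and the zero threshold
are implementation choices, not identities, and are exposed as arguments.
A one-standard-error rule (`one_se = TRUE`) trades true positives for
fewer false positives. Fold refits start from the fold's own unpenalized
fit.

## Simulators and what they emulate

`phmc_scenario()` encodes the logistic-incidence / constant-baseline Cox
design: one Bernoulli(0.5) incidence covariate with $\alpha_1 = -1$ and
$\alpha_0 \in \{2.8, 2, 0.9\}$ for average cure rates of 10/20/40%;
latency covariates Bernoulli(0.5) and Uniform(0,1) with $\beta = (1, 0.5)$
and $\lambda_0 = 1/3$. `phph_scenario()` encodes the promotion-time design
($\gamma_0 = 0.5$ or $-0.05$, $\gamma_1 = -0.1$, $\phi = (0.4, -0.3)$,
$\bar F(x) = e^{-2x}$), generated through the mixture representation: cure
with probability $e^{-\theta(X)}$ and susceptible times by the closed-form
inverse of the conditional distribution — the improper law pins the
distribution, so any algebraically equivalent generator produces the same
data distribution. Cured subjects carry an infinite latent time and can
never be events.

Censoring is Uniform$(0, c)$ with $c$ calibrated by bisection over a fixed
Monte Carlo draw of $2\times 10^5$ latent outcomes (tolerance 0.002,
deterministic given the seed). The calibration target is stated as the
fraction of **susceptible subjects that end up censored** (default 10%);
this reproduces the designs' overall censoring labels — about 30% under
20% cure, about 50% under 40% cure, about 40% under the 30%-cure selection
design. The alternative reading, the fraction of censored subjects that
are susceptible, is available via `measure =` for sensitivity analyses; it
yields lighter censoring (22%/44% in the same designs) and is not the
default for that reason.

The 20-covariate selection designs (`phmc_selection_scenario()`,
`phph_selection_scenario()`) use two Uniform(0,1), two Bernoulli(0.5) and
a 16-dimensional normal block with correlation $0.5^{|i-j|}$, shared
between components, with four nonzero coefficients per component.

These generators emulate administrative-style uniform censoring,
covariate-independent censoring, and exactly the stated covariate laws.
They do not emulate covariate-dependent or heavy-tailed censoring,
measurement error, ties (times are continuous), or model misspecification
— so passing recovery tests demonstrates correctness of the estimators
under the assumed designs, not robustness on arbitrary real data.

## Problem sizes used by the shipped studies

The package's own test suite and `scripts/acceptance.R` run desk-scale
versions of the reference studies: 100 replicates of $n = 1000$ for the
estimation study (the full study uses 500) and 20 replicates of $n = 600$
with a 15-point $\lambda$ grid for the selection study (the full study
uses 200 replicates and a finer grid). Tolerances in the tests are derived
from the Monte Carlo standard errors of the replicate counts actually
used, so the checks remain meaningful at the reduced scale.

## Known limitations

- Left truncation, interval censoring and competing risks are out of
  scope; so are confidence bands for the Kaplan–Meier curve itself.
- The jackknife pseudo-observation loop refits the statistic $n$ times;
  for $n$ beyond $\sim 10^4$ subjects a linearized (infinitesimal
  jackknife) construction would be preferable, which `pocure` does not
  implement.
- Design matrices are taken as given: interactions, splines and factor
  encodings beyond the CSV reader's one-hot rule are the caller's job.
- Post-selection inference after SCAD is not provided; reported standard
  errors apply to the unpenalized fits.
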