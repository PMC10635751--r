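---
title: "Fuzzy and classical stress-strength reliability under the Lindley model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy and classical stress-strength reliability under the Lindley model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lindleySS)
```

## The model

Strength $X \sim \mathrm{Lindley}(\theta_1)$ and stress
$Y \sim \mathrm{Lindley}(\theta_2)$ are independent, with density
$f(x;\theta) = \tfrac{\theta^2}{1+\theta}(1+x)e^{-\theta x}$ and cdf
$F(x;\theta) = 1 - \bigl(1 + \tfrac{\theta x}{1+\theta}\bigr)e^{-\theta x}$.
The Lindley law is the two-component mixture
$\tfrac{\theta}{1+\theta}\,\mathrm{Exp}(\theta) +
\tfrac{1}{1+\theta}\,\mathrm{Gamma}(2,\theta)$; `rlindley` samples it
exactly through that representation (no rejection step), which is also
how the simulation engine generates data.

The four measures of interest are

$$R = P(Y < X), \qquad
  \mathrm{MRS} = E[X - Y \mid Y < X],$$
$$\mathrm{FSS}(k) = E[\mu_A(X, Y)], \qquad
  \mathrm{FMRS}(k) = \frac{E[(X - Y)\,\mu_A(X, Y)]}{\mathrm{FSS}(k)},$$

with membership $\mu_A(x,y) = (1 - e^{-k(x-y)})\,1\{y < x\}$.  FMRS is
the membership-weighted analogue of MRS: it reduces to MRS as
$k \to \infty$ (membership $\to$ indicator), and dividing by FSS mirrors
dividing by $R$ in the classical definition.  Both properties are
enforced by tests.

## Deriving the closed forms

Every integrand above is (polynomial in $x,y$) $\times$
$e^{-\theta_1 x - \theta_2 y}$ over $\{0 < y < x\}$, hence elementary.
Substituting $t = x - y$ and integrating $y$ out leaves, with
$s = \theta_1 + \theta_2$, $A = 1/s + 2/s^2 + 2/s^3$,
$B = 1/s + 1/s^2$ and
$c = \theta_1^2\theta_2^2 / ((1+\theta_1)(1+\theta_2))$,

$$J(a) = E\!\left[e^{-(a-\theta_1)(X-Y)} 1\{Y<X\}\right] = c\Bigl(\frac{A}{a} + \frac{B}{a^2}\Bigr),
\qquad
N(a) = E\!\left[(X\!-\!Y)\,e^{-(a-\theta_1)(X-Y)} 1\{Y<X\}\right] = c\Bigl(\frac{A}{a^2} + \frac{2B}{a^3}\Bigr),$$

so that $R = J(\theta_1)$, $\mathrm{FSS}(k) = J(\theta_1) -
J(\theta_1 + k)$, $\mathrm{MRS} = N(\theta_1)/R$ and
$\mathrm{FMRS}(k) = (N(\theta_1) - N(\theta_1+k))/\mathrm{FSS}(k)$.
These derived forms are the package's source of truth: published
renderings of the same closed forms circulate with lost parentheses and
exponents, so `lindleySS` gates its own derivation twice — against the
defining-integral quadrature oracle `ss_measures_numeric()` (absolute
agreement below $10^{-6}$ on a $5\times5\times4$ grid) and against a
published 4-decimal true-value grid.  The exponential factors appearing
in the derivation cancel analytically, so the forms contain only decaying
terms and are stable for any $k$; beyond $k = 10^6$ the classical limits
are returned outright, as the difference is far below double precision.

A caveat on the reference grid: several of its 4-decimal entries are
*truncated* rather than rounded (e.g. the exact
$\mathrm{FSS}(0.5, 0.5, 20) = 0.4930927$ appears as 0.4930), so tests
compare at the printed precision ($|\Delta| \le 10^{-4}$) rather than by
re-rounding.

```{r}
ss_measures(0.5, 0.5, k = c(1, 5, 10, 20))
```

## The quadrature oracle

`ss_measures_numeric()` evaluates the defining double integrals by
nested adaptive 1-D quadrature on $[0, \infty)$ (absolute tolerance
$10^{-10}$ per pass, failure reported as an error), sharing no code with
the closed forms.  It is deliberately slow — accuracy over speed — and
exists to validate, not to serve.

## Estimators

**Maximum likelihood.**  The likelihood depends on the data only through
$\bar x$, giving the explicit root
$\hat\theta = \bigl(-(\bar x - 1) + \sqrt{(\bar x-1)^2 + 8\bar x}\bigr)/(2\bar x)$
per sample (well defined also at $\bar x = 1$, where the linear term
vanishes).  Measure estimates follow by invariance: plug
$(\hat\theta_1, \hat\theta_2)$ into the exact closed forms.

**Maximum product of spacings.**  Per sample, maximise the mean log of
the cdf increments over the order statistics.  Ties (present in real
count data) make a spacing exactly zero; following the standard
Cheng–Amin remedy the density at the tied point is substituted
(`tie = "density"`, switchable to `"none"`).  The two-sample objective is
additively separable, so each shape solves an independent 1-D problem.
A design note on the optimiser: a plain golden-section search over a
wide interval like $[10^{-8}, 10^3]$ is unreliable here, because for
large $\theta$ all cdf values round to 1 and the objective degenerates
into a flat $-\infty$ plateau that defeats bracketing.  `lindley_mps`
therefore scans a 200-point log-spaced grid first (the objective is
unimodal in practice), then polishes with `optimize` (tolerance
$10^{-10}$) inside the grid bracket.  The estimator is validated against
an independent two-stage grid search to $|\Delta\theta| < 10^{-3}$.

**Importance sampling** (gamma priors $\theta_i \sim
\Gamma(a_i, b_i)$, defaults $a_1{=}3, b_1{=}4, a_2{=}2, b_2{=}3$).  The
posterior factorises as a gamma kernel — shape $a_1 + 2n - 1$, rate
$b_1 + \sum x_i$ — times $(1+\theta_1)^{-n}$, and analogously for
$\theta_2$.  Draws come from the gamma kernels; the residual factors are
the self-normalised weights; every reported estimate is the weighted
posterior mean (squared-error loss).  One consequence of this exact
factorisation deserves emphasis: the log-weights have standard deviation
growing like $\sqrt{n}$, so the effective sample size collapses as the
samples grow — measured at $N = 10^4$ draws and $(\theta_1, \theta_2) =
(0.5, 1.5)$: ESS $\approx$ 1340 at $n{=}m{=}10$, 70 at $n{=}m{=}30$, 15
at $n{=}m{=}50$, and below 10 by $n{=}m{=}200$.  The implementation
treats ESS < 10 as a diagnostic error rather than returning a
one-draw answer; tests exercise IS at $n = m = 30$, where the algorithm
is healthy.  For larger samples, use MCMC.

**MCMC.**  Each univariate full conditional
$\pi(\theta_1 \mid x) \propto \theta_1^{c-1}(1+\theta_1)^{-n}
e^{-d\theta_1}$ (noninformative prior $\pi(\theta_i) \propto 1/\theta_i$:
$c = 2n$, $d = \sum x_i$; gamma prior: $c = a_1 + 2n - 1$,
$d = b_1 + \sum x_i$, matching the IS target exactly so the two
algorithms are mutually checkable) is sampled by random-walk Metropolis
on $\log\theta$.  The Jacobian of the log transform is included in the
acceptance ratio, so the chain targets the stated density in $\theta$,
not in $\log\theta$ — verified by matching chain histograms against the
numerically normalised conditional.  The Gaussian step scale is adapted
every 50 iterations during burn-in toward ~35% acceptance and then
frozen; defaults are 10000 retained draws after 1000 burn-in, and a
post-adaptation acceptance rate outside [0.05, 0.95] raises a warning.
The noninformative $c = 2n$ is not the $a,b \to 0$ limit of the
gamma-prior $c$ (they differ by one power of $\theta$); both conventions
are retained deliberately because each is the established form for its
prior family in this literature, and the prior kind is always an
explicit configuration choice.

## Simulation engine

`ss_simstudy` mirrors the usual study design for this model: sizes
$(n,m) \in \{(5,5), (10,10), (30,30), (50,50), (100,100)\}$, parameter
pairs $(0.5,0.5), (0.5,1.5), (2,0.5), (1.5,1.5)$, $k \in \{1,5,10,20\}$,
default 1000 replications.  Bias and MSE are measured against the
*analytic* true value of each measure at the generating parameters.
Each cell draws its own seed (master seed + cell offset), so cells are
independently reproducible; per-replication estimator failures are
counted and excluded, never silently dropped; Monte Carlo standard
errors accompany every summary so scaled-down runs stay interpretable.
The generator emulates clean i.i.d. Lindley data — no censoring,
rounding, contamination or dependence — so passing trends (MSE
decreasing in $n$, $\hat R$ centred at $1/2$ under the symmetric design
by the exchangeability of $\hat\theta_1, \hat\theta_2$) demonstrate
estimator correctness under the model, not robustness to violations of
it.

## Goodness of fit and the bundled application

`ad_statistic`/`cvm_statistic` are the standard $A^2$ and $W^2$ EDF
statistics at a fitted Lindley cdf (cdf values clipped away from
$\{0,1\}$ by $10^{-300}$ before logs).  Because $\theta$ is estimated,
asymptotic null tables are invalid; p-values come from a parametric
bootstrap (default $B = 1000$): simulate from the fitted law, refit by
the closed-form MLE, recompute.  A calibration test confirms approximate
uniformity of the p-value under the null (scaled-down study:
150 null datasets of $n = 25$ at $B = 99$ — sizes chosen to keep the
default suite fast while leaving the Kolmogorov–Smirnov check sharp
enough to catch miscalibration).

`endocrine_application()` analyses the bundled tumour-count data
($n = 23$ radiotherapy, $m = 24$ chemotherapy).  Its report prints our
estimates beside previously reported values for the same data.  Two
discrepancies in those reference values are documented rather than
hidden: their "MLE" row is inconsistent with the closed-form Lindley
MLE on the same data (which gives $R = 0.7849$, matching the reference
*MPS* entry instead), and their Anderson–Darling statistics are not
reproduced by the standard $A^2$ at either the MLE or MPS fit (we obtain
0.96/1.01 against reported 1.04/1.13; the Cramér–von Mises values do
agree within 0.05).  The reference estimator and p-value provenance are
unstated, so these rows serve as context, never as ground truth.

## Numerical choices, in brief

* Survival/cdf evaluated in the stable product form; underflow for
  $\theta x \gtrsim 745$ yields exact 0/1 tails.
* Quantiles by monotone bisection-free `uniroot` inversion with doubling
  upper bracket; inversion verified to $10^{-10}$ or an error is raised.
* Sample validation rejects non-positive entries with row-indexed
  errors, at the type boundary (`read_sample_csv`, fit entry points).
* Degenerate inputs: single-observation samples are legal everywhere the
  theory permits ($n \ge 1$ for estimation, $n \ge 2$ for EDF
  statistics); empty samples are accepted by the low-level IS routine
  only, where the draws then follow the stated $n = 0$ kernel
  Gamma$(a_i - 1, b_i)$.
* Test problem sizes (e.g. $10^5$-draw chains for density matching,
  1000-replication ladders, a $5\times5\times4$ oracle grid) were chosen
  as the smallest sizes at which each check is decisively sharper than
  its Monte Carlo noise.

## Known limitations

* Interval/credible estimation is out of scope; point estimates only.
* Only the exponential membership family is implemented.
* The importance sampler inherits the weight degeneracy of its printed
  algorithm (see above); it is a small-sample tool.
* The generalized, weighted and two-parameter Lindley variants, censored
  data, and multicomponent systems are not covered.
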