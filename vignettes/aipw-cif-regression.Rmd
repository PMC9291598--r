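---
title: "Doubly robust cumulative incidence regression with interval censoring and missing event types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubly robust cumulative incidence regression with interval censoring and missing event types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aipwcif)
```

## The problem

In cohort studies with competing risks — say, death while in care versus
disengagement from care after treatment initiation — the quantity of direct
clinical interest is often the cumulative incidence function (CIF),

$$F_j(t; z) = \Pr(T \le t,\ \epsilon = j \mid Z = z),$$

the probability of failing from cause $j$ by time $t$ in the presence of
the competing causes. Two complications are endemic to registry and
electronic-health-record data:

1. **Interval censoring.** Events are detected at clinic visits, so the
   event time is only known to lie between the last visit before the event
   ($V$) and the first visit after it ($U$). $V = 0$ gives left censoring;
   if the event is never detected the subject is right-censored
   ($U = \infty$).
2. **Missing event types.** For a subset of events the *type* is never
   ascertained — e.g. a patient lost to follow-up may have died
   (unreported) or disengaged. Crucially, this missingness affects events
   only: right-censored status is always observed.

Dropping events with unknown type (a complete-case analysis) selectively
removes events and keeps all censored subjects, which biases the estimated
covariate effects. This package implements a doubly robust, augmented
inverse-probability-weighted (AIPW) sieve maximum-likelihood estimator for
this setting, together with complete-case (CC) and multiple-imputation
(MI) comparators and a synthetic-data generator for study-scale Monte
Carlo evaluation.

## Model

Each CIF is modeled semiparametrically through the generalized odds rate
transformation family:

$$g_{\alpha_j}\{F_j(t; z)\} = \phi_j(t) + \beta_j^\top z, \qquad
g_\alpha(F) = \begin{cases}
\log\dfrac{(1-F)^{-\alpha} - 1}{\alpha}, & \alpha > 0,\\[4pt]
\log\{-\log(1-F)\}, & \alpha = 0,
\end{cases}$$

where $\phi_j$ is an unspecified strictly increasing baseline transform
and $\beta_j$ are cause-specific regression coefficients. $\alpha = 0$
gives the Fine–Gray proportional subdistribution hazards model and
$\alpha = 1$ the proportional odds model. The exponents $\alpha_j$ are
user-fixed model indices (default 1), not estimated — they select a model,
as is conventional for this family.

Each $\phi_j$ is approximated over a monotone B-spline sieve
$\phi_j(t) = \sum_{s=1}^{N_n + m} \gamma_{js} B_{s,m}(t)$ of order $m$
(default 4, cubic) with $N_n \approx n^{\nu}$ interior knots placed at
empirical percentiles of the pooled finite observation times
$\{V_i, U_i\}$. The default rate exponent $\nu = 1/5$ corresponds to
$\nu = 1/(1+2p)$ with smoothness $p = 2$; both $m$ and $\nu$ (or a fixed
interior-knot count) are exposed in `aipw_control()`. Monotonicity is the
restriction $\gamma_{j1} < \cdots < \gamma_{j,N_n+m}$.

## The two-stage AIPW estimator

With fully observed types, the (scaled) log-likelihood of the observed
data is

$$\ell(\theta) = \frac1n \sum_i \Big[ \textstyle\sum_j \Delta_{ij}^{(1)}
\log\{F_j(U_i) - F_j(V_i)\} + \sum_j \Delta_{ij}^{(2)} \log F_j(U_i)
+ (1-\Delta_i) \log\{1 - \sum_j F_j(V_i)\} \Big],$$

where $\Delta^{(1)}, \Delta^{(2)}$ indicate interval- and left-censored
events. When types are missing at random (MAR) given the observed data
$O = (U, Z, A)$ — where $A$ are auxiliary covariates predictive of
ascertainment but not of scientific interest — the unobservable
cause-specific indicators are replaced by AIPW pseudo-indicators

$$\tilde\Delta_{ij}^{(l)} = \frac{R_i}{\rho(O_i)}\Delta_{ij}^{(l)}
- \frac{R_i - \rho(O_i)}{\rho(O_i)}\,\Delta_i^{(l)}\,\pi_j(O_i),$$

built from two parametric working models fitted in a first stage:
$\rho(O) = \Pr(R = 1 \mid \Delta = 1, O)$, a binary logistic model fitted
on all events, and $\pi_j(O) = \Pr(\epsilon = j \mid \Delta = 1, O)$, a
binary (k = 2) or multinomial (k > 2) logistic model fitted on the events
with observed type. The augmentation is applied to the record's observed
censoring class $\Delta_i^{(l)}$ (the class is always observed; only the
type can be missing), which makes the weights conserve mass:
$\sum_{j,l} \tilde\Delta_{ij}^{(l)} = 1$ for every event. The second
stage maximizes the weighted objective over the sieve space. The
estimator is *doubly robust*: it is consistent when either $\rho$ or
$\pi$ is correctly specified, not necessarily both. Both defaults use the
linear design intercept + $U$ + $Z$ + $A$; the response model may include
$V$ if the user overrides the formula, but by default $R$ is assumed to
depend on the diagnosis time $U$ only, which is the natural working
assumption for visit-driven ascertainment.

When no event type is missing the pseudo-indicators reduce to the
observed indicators and `fit_aipw()` short-circuits to the complete-data
sieve MLE (`fit_sieve()`), with a message.

### Constrained optimization

Two constraints matter. Monotonicity of each $\phi_j$ is enforced by an
unconstrained reparameterization
$\gamma_1 = r_1,\ \gamma_{s+1} = \gamma_s + \exp(r_{s+1}) + \delta$
with a minimum gap $\delta = 10^{-6}$ that keeps "strictly increasing"
numerically meaningful. The joint constraint
$\max_z \sum_j F_j(b; z) < 1$ (at the right end $b$ of the sieve domain,
with the maximum over the *observed* covariate rows — an unrestricted
maximum is unbounded for continuous covariates) is handled by a
logarithmic barrier with a short continuation schedule
($\mu = 10^{-2}, 10^{-4}$), warm-starting each stage. Because the hard
row-maximum has kinks where the argmax row switches — on which quasi-Newton
iterations can stall when the solution hugs the boundary — the barrier
uses a log-sum-exp upper bound on the row totals (temperature 0.005).
The bound dominates the hard maximum, so a feasible smoothed margin
implies the hard constraint; the hard margin is re-checked at every
returned solution. Optimization uses `stats::nlminb` (a quasi-Newton
trust-region method) with fully analytic gradients, chain-ruled through
the monotone reparameterization; a central finite-difference check is
part of the test suite.

One property of the weighted objective deserves note: AIPW
pseudo-indicators can be negative, and a negatively weighted
$\log F_j(U_i)$ term *increases* the objective as that probability is
pushed toward zero, so the objective can diverge logarithmically along
directions that send a spline coefficient to $-\infty$. The consistency
theory assumes a compact parameter space, and the optimizer makes that
operational with generous box constraints on the working parameters
($|\gamma_{j1}| \le 15$, log-gaps in $[-25, 3.5]$, $|\beta| \le 10$ —
far beyond any plausible effect on the transformed scale). A solution
on a box face corresponds to a baseline CIF numerically indistinguishable
from 0 at the left boundary, and convergence is assessed by the
projected gradient.

Initialization sets $\beta = 0$ and baseline CIFs rising from 0.01 at
$a = 0$ to $0.3/k$ at $b$ — always feasible. On nonconvergence the fit is
restarted (default 3 times) from jittered initials; failure after
restarts raises an error carrying the best iterate. Convergence uses a
relative objective tolerance of $10^{-10}$ plus a gradient-norm check;
fitted response probabilities used as inverse weights are clipped to
$[10^{-3}, 1-10^{-3}]$ (logged when active) because near-zero fitted
response probabilities would otherwise destabilize the objective.

### Variance estimation

Standard errors come from the nonparametric bootstrap: resample subjects
with replacement, rerun the *full two-stage* fit, and take the standard
deviation of the replicate coefficients; 95% intervals are Wald,
$\hat\beta \pm 1.96\,\mathrm{SE}$. For double-sampling designs in which
the number of type-ascertained cases is fixed by design, a stratified
variant resamples separately within the observed-type events, the
missing-type events, and the right-censored pool, preserving stratum
sizes. Replicates that fail to converge are dropped and counted
(warning above 20% failures, error above 50%).

### Comparators

`fit_cc()` drops the missing-type events and runs the complete-data sieve
MLE — the strategy whose selection bias motivates the method. `fit_mi()`
imputes each missing type from the fitted event-type model, fits the
complete-data MLE on each of $M$ completed datasets (default 5), and
pools by Rubin's rules ($\bar W$ within, $B$ between,
$T = \bar W + (1+1/M)B$). Whether the imputation-model parameters should themselves be drawn per
imputation is a genuine design choice; both modes are provided, and the
default is *proper* MI
(draw $\psi^*$ from the asymptotic normal of $\hat\psi$), the variant
under which Rubin's rules are calibrated. Within-imputation variances
use the same bootstrap engine.

## The synthetic-data generator

`simulate_crdata()` emulates the Monte Carlo design used throughout the
package's own evaluation:

* two causes with proportional-odds CIFs and improper Gompertz baselines
  $\exp\{\phi_j(t)\} = -(\tau_j/\rho_j)\{1 - e^{\rho_j t}\}$, with
  $(\tau_1, \rho_1) = (0.40, -0.60)$, $(\tau_2, \rho_2) = (0.75, -0.50)$;
* $\beta = (\beta_{11}, \beta_{12}, \beta_{21}, \beta_{22}) =
  (0.5, -0.3, -0.5, 0.3)$ on $Z_1 \sim \mathrm{Bernoulli}(0.4)$ and
  $Z_2 \sim N(0,1)$;
* an auxiliary variable $A = I(\epsilon = 1) + N(0, 1)$, associated with
  the true type and hence informative for the missingness models;
* visit times with independent $\mathrm{Exp}(3)$ gaps (one visit every
  four months on average), administratively ended at 3 years — yielding
  about 13.6% right censoring; a fixed visit grid is available for
  designs with discrete observables;
* a logistic MAR response model
  $\mathrm{logit}\Pr(R = 1 \mid O) = \xi_0 + 0.5U - 0.5Z_1 + 0.6Z_2 +
  \xi_4 A$ applied to events; $(\xi_0, \xi_4) = (0.60, 0)$ gives a 30%
  missingness rate among events.

Under these parameters the two subdistribution plateaus are exactly
complementary ($F_1(\infty;z) + F_2(\infty;z) = 1$ for every $z$), so
the latent type is drawn from the plateau probabilities and the latent
time by closed-form inversion of the conditional subdistribution. For
user-supplied parameters with total plateau mass below one, the
remainder is treated as a cured fraction (never-event, right-censored at
study end); mass above one is a configuration error, since no rule for
renormalizing is implied by the design. Subjects whose first visit falls
beyond the administrative end are retained as right-censored with
$V = 0$; dropping them would distort the covariate distribution. The
missingness draw uses the realized detection visit $U$. Missingness
rates are computed *among events*: right-censored subjects can never
have a missing type.

Higher-missingness regimes are specified by their target rate rather
than by an intercept value: `calibrate_missingness()` solves for $\xi_0$
by root-finding on a large calibration sample, holding the slopes fixed
(the 50% scenario in the package's own studies is produced this way).

Randomness is consumed from a fixed-size block of uniforms per subject,
so a seed yields a bit-identical dataset, extending $n$ preserves the
earlier subjects, and Monte Carlo replicates parallelize reproducibly
(per-replicate seeds are derived from the master seed by a counter
scheme, so results are identical for any worker count).

What the generator does *not* emulate: covariate-dependent or
informative visit processes, truncation, time-varying covariates,
exactly observed event times mixed with intervals, and missingness that
depends on unobservables (MNAR). Passing tests therefore demonstrate
correctness of the estimator under independent, noninformative interval
censoring and MAR types — not robustness to violations of those
assumptions.

## What the package's own experiments compute

The test suite and the acceptance script rerun the Monte Carlo pipeline
at desk scale, as this package's own precision/runtime choice (a
full-scale study would use 1000 replicates with 100 bootstrap
replications):

* generator checks at $n = 10^5$ (right-censoring and missingness rates);
* point-estimation studies with 250 replicates at $n = 200$ (all three
  methods) and 400 replicates at $n = 400$ (double-robustness checks) in
  the tests, and 600 replicates per scenario in the acceptance script;
* a token-scale coverage experiment (50 replicates × 50 bootstrap
  refits) for interval coverage and SE calibration;
* a designed double-robustness flip: discrete observables (binary
  covariate, fixed visit grid) where a saturated event-type model is
  correct by construction while the response model is deliberately
  misspecified as intercept-only.

A small worked run:

```{r example, eval = FALSE}
scenario <- sim_scenario()
dat <- simulate_crdata(200, scenario, seed = 1)
fit <- fit_aipw(dat, nboot = 100, seed = 1)
tidy(fit)
autoplot(fit)
```

## Known limitations

The estimator is exercised for two event types; the data layer and the
event-type model accept $k > 2$ (multinomial), but the full pipeline is
validated for $k = 2$. The weighting is doubly robust but not
semiparametrically efficient, and no analytic (profile-likelihood)
variance is provided — the bootstrap is the supported route. Percent
bias is undefined at zero truth; use absolute bias there. The sieve
domain ends at the largest finite observation time; predictions beyond
it are refused rather than extrapolated.
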