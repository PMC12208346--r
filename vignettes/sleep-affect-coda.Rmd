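---
title: "Multilevel compositional analysis of sleep architecture and morning affect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel compositional analysis of sleep architecture and morning affect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A night in bed divides into four exhaustive parts: total wake time in bed
(TWT: sleep-onset latency plus wake after sleep onset), light sleep (NREM
stages 1–2), slow-wave sleep (SWS, NREM 3) and REM sleep. Because the four
parts sum to the time in bed, they are *compositional*: only relative
information is meaningful, and one stage can only grow at the expense of
others. Nightly EEG recordings over a daily-diary study additionally make
the data *multilevel* — stable differences between people coexist with
night-to-night deviations within a person.

`sleepcoda` implements the full analysis chain for relating such nightly
compositions to next-morning affect (the four circumplex domains: high/low
arousal positive/negative affect, each a 1–5 questionnaire mean):
log-ratio geometry, between-/within-person decomposition, Bayesian
multilevel models with random compositional slopes, predictive model
comparison, and posterior time-reallocation ("substitution") estimates.

## Compositional geometry

Compositions are carried internally as proportions, with time in bed kept
separately; minutes are reconstructed on demand. This makes the scale
invariance of every log-ratio operation explicit.

A 4-part composition is mapped to 3 unconstrained coordinates by the
isometric log-ratio (ilr) transform $z = V \log x$, where the $3 \times 4$
contrast matrix $V$ comes from a *sequential binary partition* (SBP): a
hierarchy of binary splits of the parts. A split with $r$ parts on the
positive side and $s$ on the negative side contributes the balance
coefficients $+\sqrt{s/(r(r+s))}$ and $-\sqrt{r/(s(r+s))}$. The default
partition is

1. wake in bed vs all sleep,
2. light sleep vs deep sleep (SWS + REM),
3. SWS vs REM,

chosen for interpretability only: the package's substitution estimates are
numerically invariant to the SBP (an orthogonal rotation of the
coordinates, absorbed exactly by the linear model), and the test suite
verifies this both analytically and by refitting. Any valid SBP can be
passed instead.

Zero minutes in a stage (possible for SWS or REM on a bad night) are
handled by multiplicative replacement: each zero part is set to
$\delta = 0.5$ min — half of a 1-minute scoring epoch — and the observed
parts are scaled down proportionally so the night's total and the ratios
among observed parts are preserved. $\delta$ is configurable.

## Between- and within-person coordinates

For person $i$ with nights $x_{ij}$, the person-level coordinates are
$b_i = \mathrm{ilr}(g_i)$ with $g_i$ the geometric-mean composition of the
person's nights (the compositional centre — the arithmetic mean in ilr
space), and the nightly deviation is $w_{ij} = \mathrm{ilr}(x_{ij}) - b_i$.
The decomposition is exact ($b_i + w_{ij}$ reproduces each night) and
$w_{ij}$ averages to zero within person. Nights with any missing stage are
dropped listwise before decomposition; imputation of multilevel
compositions is out of scope.

The grand reference composition used by the substitution analysis is the
geometric mean *over persons* of the person centres, so that every person
counts equally regardless of how many usable nights they contributed; a
pooled-nights variant is available.

## The candidate models

For each affect outcome $y_{ij}$ (morning affect of person $i$ after night
$j$) four nested Gaussian multilevel models are fitted:

* **a** — covariates only, random person intercept;
* **b** — a + the 3 between-person coordinates $b_i$;
* **c** — a + the 3 within-person coordinates $w_{ij}$, with correlated
  random slopes on $w$;
* **d** — a + both coordinate sets, with the variant-c random structure.

All variants adjust for time in bed, the previous night's pre-sleep score
of the same affect domain (so the composition predicts *change* in
affect), weekend, circadian misalignment (composite phase deviation,
consumed as a ready-made covariate), age, gender, ethnicity, subjective
social status and BMI. Numeric covariates are mean-centred; categorical
covariates enter as indicator contrasts against their most frequent level
(a deterministic rule, since the reference level is substantively
arbitrary). A time-in-bed-by-composition interaction can be switched on to
test moderation by sleep opportunity; it adds products of centred time in
bed with every coordinate column.

The affect outcomes are treated as continuous with an identity link:
substitution effects are reported as additive differences on the 1–5
response scale, which is the scale on which the results are interpreted.
Ordinal or beta likelihoods are out of scope.

### Priors

The priors are weakly informative and resolved against the observed data
scale at fit time:

* coefficients: Normal$(0, (5\,\mathrm{sd}(y)/\mathrm{sd}(x_j))^2)$;
* intercept: Student-t$(3, \mathrm{median}(y), 2.5\,\mathrm{mad}(y))$;
* residual and group SDs: half-Student-t$(3, 0, 2.5\,\mathrm{sd}(y))$;
* covariance of the correlated random intercept + slopes: inverse-Wishart
  with identity$\times\mathrm{sd}(y)^2$ scale and $Q+1$ degrees of freedom
  (the heavy-tailed, weakly informative end of that family). An LKJ
  correlation prior would be the other natural choice here; the Wishart
  family was chosen because it keeps the Gibbs updates conjugate in the
  JAGS backend.

All scale multipliers are configurable through `prior_spec()`.

### Sampling and convergence

Fitting runs in JAGS with the `glm` module, which block-updates the
conjugate fixed-effect layer. The Student-t intercept prior is written as
a normal–gamma scale mixture for the same reason: it keeps the intercept
inside the conjugate block (a plain t prior degraded the intercept's
effective sample size by two orders of magnitude). Chains are seeded
deterministically from the user seed, so identical spec + data + seed
reproduce the draws bit for bit.

Desk defaults are 4 chains × (500 warmup + 500 sampling) = 2000 draws,
which keeps a variant-d fit on a 60-person panel near ten seconds; the
study-scale setting (8 chains × 1000 + 5000 = 40 000 draws) is one
`mcmc_control()` call away. Convergence is gated on the usual thresholds —
potential scale reduction $\hat R < 1.05$ and effective sample size
$> 400$ over all monitored structural parameters. A fit failing the gate
is returned with `converged = FALSE` and a warning, never discarded
silently; at small panel sizes the random-slope SDs are typically the last
parameters to clear the ESS gate.

### Bayesian $R^2$

Per posterior draw, conditional $R^2 = \mathrm{var}(\mu)/
(\mathrm{var}(\mu) + \sigma^2)$ with $\mu$ the full linear predictor
(fixed + person effects). Marginal $R^2$ credits only the fixed effects
and counts person-level variation as unexplained:
$\mathrm{var}(X\beta)/(\mathrm{var}(X\beta) + \mathrm{var}(Zu) +
\sigma^2)$. With this definition conditional $\ge$ marginal up to Monte
Carlo error, and on between-dominant outcomes (affect ICC around 0.6) the
two separate widely, as expected.

## Model comparison

`psis_loo()` estimates the expected log pointwise predictive density
(elpd) by Pareto-smoothed importance sampling: per observation, the
importance ratios $1/p(y_i\mid\theta_s)$ have their largest 20% replaced
by expected order statistics of a generalized Pareto distribution fitted
by the Zhang–Stephens profile-likelihood method (with the usual weak-prior
shrinkage of the shape), capped at the raw maximum. Observations with
Pareto shape $\hat k > 0.7$ trigger a reliability warning — common for
hierarchical models when a person contributes few nights, and worth
heeding. The pointwise log-likelihood is conditional on the fitted person
effects, matching the likelihood the model was estimated with.

Candidates are ranked by $\Delta\mathrm{elpd}$ from the best model;
models within 2 are labelled *strong*, models more than 10 behind *poor*.
`stacking_weights()` solves the simplex-constrained log-score stacking
program $\max_w \sum_i \log \sum_k w_k e^{\mathrm{lpd}_{ik}}$ — a concave
problem solved by bounded quasi-Newton ascent on a softmax parametrisation
from a uniform start, so flat optima (identical models) return the
symmetric solution deterministically. A squared-error variant that stacks
leave-one-out point predictions is also provided; the log score is the
default because it is the scoring rule the stacking methodology is built
on.

The pipeline's post-hoc rule mirrors the selection criterion of the
analysis it reproduces: substitution runs at the between-person level only
if a candidate containing the between coordinates (b or d) has stacking
weight > 0 (beyond two-decimal rounding, i.e. $\ge 0.005$) *and*
$\Delta\mathrm{elpd} > -2$; likewise for the within level via c or d.

One property of observation-level LOO is worth stating explicitly: with
many nights per person, a random intercept predicts a held-out night of a
*known* person essentially as well as any between-person predictor, so
models a and b become predictively indistinguishable even when the
between-person effects are real and large. The comparison has power for
the between-person terms only when persons contribute few nights (or when
predictions for new persons are the target). The package's selection-rule
test therefore uses a 60-person × 4-night design.

## Substitution analysis

`reallocate_minutes()` moves $t$ minutes from a donor stage to a recipient
stage, leaving the other stages and the total untouched. For each grid
point (all 12 ordered stage pairs, $t = 1,\dots,60$ by default — the two
directions are distinct because the inverse-ilr map is non-linear in
minutes), the posterior difference in expected affect between the
reallocated and the unchanged reference composition is summarised by its
mean, equal-tailed 95% credible interval, and a significance flag (interval
excludes zero).

* **Between level**: $b$ moves from $\mathrm{ilr}(\mathrm{ref})$ to
  $\mathrm{ilr}(\mathrm{ref}^\ast)$, $w = 0$ — comparing two hypothetical
  persons whose habitual compositions differ by the reallocation.
* **Within level**: $b$ stays at the reference, $w$ moves from 0 to
  $\mathrm{ilr}(\mathrm{ref}^\ast) - \mathrm{ilr}(\mathrm{ref})$ — one
  person sleeping differently than usual for a night.

Predictions are population-level: random intercepts and slopes sit at
their zero mean, so estimates describe a typical person. Covariates sit at
a deterministic reference row — centred numerics at their sample means,
indicators at the reference level. Grid points that would exhaust the
donor stage are skipped with a message, never clamped or extrapolated.
Both levels are exactly linear in the coordinate difference given the
draws, which is what makes the SBP-invariance and closed-form oracle tests
exact to numerical precision.

Standardized differences divide the posterior mean by a configurable
scale: the observed outcome SD (default), the model's between-person SD
(random-intercept SD), or the within-person residual SD. The published
analyses this package generalises do not state their divisor, and no
single candidate reproduces printed standardized values from the
unstandardized ones; all three are therefore exposed and none is claimed
as canonical.

## The synthetic-data generator

`generate_sleep_data()` produces panels with the statistical structure the
pipeline targets, so every stage is testable without any data download:

* **Compositions** are logistic-normal: person means
  $b_i \sim N_3(\mu_b, \Sigma_b)$ in ilr space around the grand mean
  composition (13% wake, 43% light, 21% SWS, 23% REM), nightly deviations
  $w_{ij} \sim N_3(0, \Sigma_w)$. Generating in ilr space keeps every
  night strictly positive by construction and makes the generating truth
  analytic in the same coordinates the models use. Defaults
  $\Sigma_b = 0.0315\,I$, $\Sigma_w = 0.0585\,I$ give coordinate ICCs of
  $0.0315/0.09 = 0.35$, the centre of the within-dominant range reported
  for sleep architecture (0.29–0.40), with a total coordinate SD of 0.3 —
  night-to-night proportion swings of a realistic few percentage points.
* **Time in bed** is Normal(448.66, 95.47) minutes, floored at 180 (a
  config whose floor would truncate more than 1% of draws is rejected as
  infeasible).
* **Affect** follows the variant-d generating model: intercept 2.5 +
  composition effects + covariate effects + person intercept
  (SD 0.45) + person slopes on $w$ (SD 0.05 each) + residual (SD 0.35),
  clipped to [1, 5]. The intercept/variance choices put the outcome ICC
  near $0.45^2/(0.45^2+0.35^2) \approx 0.62$ — inside the between-dominant
  0.55–0.67 band reported for affect — while keeping clipping below about
  1% of draws. Default composition effects are modest (between 0.20,
  −0.15, 0.10; within 0.08, −0.05, 0.06 per unit ilr); recovery
  experiments pass larger values explicitly.
* **Covariates**: pre-sleep affect is itself two-level (person SD 0.5,
  daily SD 0.4) with a carry-over coefficient of 0.15; weekends follow
  each person's calendar with staggered study starts (person $i$ begins on
  weekday $i \bmod 7$), so even short panels contain weekend nights;
  binary demographics (77% female, 85% Asian, matching the target
  population) are assigned in exact proportion with both levels guaranteed
  from 2 persons up, keeping contrasts estimable in small test panels.
* **Missingness** is completely at random: 4% of sleep nights (masked as
  whole nights) and 19% of morning reports (all four domains jointly),
  the availability pattern of the emulated protocol. MCAR suffices
  because the analysis is complete-case.

What the generator deliberately does **not** emulate: night-to-night
autocorrelation (REM rebound), sleep-staging measurement error,
informative missingness, floor effects in negative affect, or intra-night
stage sequencing. Passing tests therefore demonstrate that the pipeline
recovers the truth of a well-specified multilevel compositional world, not
that it is robust to those violations.

A note on parameter recovery: the models use each person's *sample*
geometric mean as $b_i$, which differs from the generating $b_i$ by the
mean of a finite number of nightly deviations. With 10 nights this
measurement error attenuates between-person coefficients by a factor of
roughly $\Sigma_b/(\Sigma_b + \Sigma_w/10) \approx 0.84$ under the default
calibration. The recovery experiments (60 persons × 10 nights, 10
replicates) absorb this: 95% interval coverage of the six composition
effects stays at or above 85%, and the replicate-averaged posterior means
sit well within half a posterior SD of the truth.

## Numerical and design choices

* Inverse ilr uses a log-sum-exp guard, so arbitrarily large coordinates
  cannot overflow.
* Designs are checked for constant columns and rank deficiency before
  fitting; failures name the offending column.
* The problem sizes in the test-suite experiments (panels of 12–60
  persons, 4–10 nights, 2000 draws; a 500-person panel for calibration
  checks) are the package's chosen trade-off between Monte Carlo precision
  and a suite that runs in minutes; all of them are config parameters, not
  constants.
* Every stochastic entry point takes a seed, and the pipeline derives all
  stage seeds from one master seed, so a full run is reproducible
  end-to-end.
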