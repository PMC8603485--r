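---
title: "Design, endpoints and Bayesian analysis of an adherence pilot trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design, endpoints and Bayesian analysis of an adherence pilot trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adherepilot)
```

This vignette documents the statistical models behind `adherepilot`, the
assumptions they make, the numerical choices in the implementation, and what
the package's synthetic-data experiments do and do not establish.

## The two-stage group-sequential design

The design engine targets a two-arm trial with one interim analysis at half
of the maximum information. Writing $Z_k$ for the one-sample z statistic at
analysis $k$ with information fraction $t_k$, the canonical joint law is
Gaussian with $E[Z_k] = \delta\sqrt{t_k}$ and
$\mathrm{corr}(Z_j, Z_k) = \sqrt{t_j/t_k}$, where $\delta = \theta\sqrt{n_{\max}}$
and $\theta = (z_{1-\alpha/2} + z_{1-\beta})/\sqrt{n_{\mathrm{fix}}}$ is the
fixed-design drift per $\sqrt{n}$. Type-I error is spent on the efficacy
(upper) bound by the Hwang–Shih–DeCani family
$f(t;\gamma) = \mathrm{err}\,(1-e^{-\gamma t})/(1-e^{-\gamma})$ with
$\gamma = -4$ at one-sided $\alpha = 0.025$; type-II error is spent on a
*binding* futility (lower) bound with $\gamma = -2$ at $\beta = 0.2$.
Negative $\gamma$ back-loads spending, which is what makes the interim
efficacy bound strict ($\approx 2.75$) while the binding futility bound is
permissive ($\approx 0.40$).

`solve_boundaries()` solves, stage by stage, the upper bound from the
α-schedule under the null (with the futility bound truncating the
continuation region, because it is binding) and the lower bound from the
β-schedule under the drift; an outer root-find on $n_{\max}$ makes the two
bounds meet at the final analysis, which simultaneously fixes total power at
$1-\beta$. Crossing probabilities come from the classical recursion for the
sub-density of the sequential statistic over the continuation region.

Numerical choices:

* quadrature: trapezoid rule on 601 nodes per stage over the continuation
  interval (truncated at ±8 SD when a bound is infinite). On this problem the
  trapezoid error is far below the $10^{-6}$ root-finding tolerance; a test
  cross-checks the recursion against $10^6$ plain Monte-Carlo draws of the
  bivariate statistic.
* root finding: `uniroot` at tolerance $10^{-6}$ on probabilities, for the
  per-stage bounds and for $n_{\max}$.
* final-stage closure: the efficacy and futility bounds are set exactly equal
  at the last analysis (the root-finder leaves a gap within its tolerance, of
  either sign, which is collapsed to the efficacy bound).
* sample-size rounding: per-group counts are rounded up (16 and 32 per group
  here, so 30 and 62 degrees of freedom for the two-sample t tests), while
  expected-sample-size summaries use the solved, unrounded $n_{\max}$.

Because the trial analyzes t statistics rather than z statistics, the solved
z-scale bounds are mapped to the t scale by quantile substitution
$t = F^{-1}_{\mathrm{df}}(\Phi(z))$. This preserves tail probabilities under
the null exactly, but *not* under a noncentral alternative — which is why the
package ships both a normal-theory oracle (`oc_analytic_check()`) and an
exact noncentral-t oracle for the interim decision cells
(`oc_exact_interim()`). The simulation tests use the exact oracle for the
interim cells under the alternative, where the normal approximation is off
by up to about 0.03 at the strict efficacy bound.

## Operating-characteristics simulation

`simulate_oc()` draws unit-variance Gaussian outcomes with a between-group
mean difference equal to the standardized effect, computes pooled-variance
two-sample t statistics at 16/group (interim) and the accumulated 32/group
(final), and follows the decision path: stop for futility below the interim
lower bound, claim success above the interim upper bound, otherwise continue
and claim success above the final bound. The final statistic uses all
accumulated observations, not a stagewise increment, matching how the trial
would actually be analyzed. Each replicate runs on its own RNG stream seeded
by `seed + replicate`, so enlarging the simulation never reshuffles earlier
replicates, and identical seeds give bit-identical results. Both the
cumulative efficacy-claim probability (interim + final) and the final-only
probability are reported; the cumulative one is the design's one-sided
type-I error under the null.

## Endpoint derivations

* **% pill count** is the printed dispensing formula, one prescribed pill
  per day: $100(\text{prescribed} - \text{remaining})/\text{days}$. Late
  returns can push it above 100; the value is reported as computed, and
  clamping to 100 happens only at the logit-transform step (and is counted).
* **MEMS on-schedule %**: the first cap opening of each calendar day is the
  dose event (later openings are treated as curiosity openings and ignored).
  A least-squares line of clock time on day index estimates the usual dosing
  time per day; a scheduled day is on schedule if its opening lies within
  ±6 h of the line, *inclusive* (an epsilon of 1e-9 h keeps an exactly-6 h
  residual from being dropped by floating-point noise). Days without an
  opening are missed. Clock times are unwrapped around the sample median
  before the fit so a near-midnight habit does not split into 0 h/24 h
  clusters; this also makes the endpoint invariant to uniform clock shifts.
  Fewer than two dosing days cannot support the line fit: the endpoint is 0
  with a warning, consistent with treating an unusable log as non-adherence.
* **QIDS-SR**: remission is a total score of at most 5 — the conventional
  QIDS-SR remission cut, exposed as a configurable threshold since wordings
  of "a score of 5" vary — and response is at least a 50% reduction from
  baseline, boundary inclusive.
* **Intention-to-treat imputation**: from the withdrawal week onward, both
  adherence endpoints are 0 and the row is flagged; after imputation every
  randomized participant has one row per scheduled visit (weeks 2, 4, 8).
  QIDS values are not zero-imputed — depression scores of withdrawn
  participants are simply missing, and the mixed model conditions on
  observed rows.

## The synthetic trial generator

The pilot's participant-level records are not deposited, so the package
generates trials with the structure the analysis assumes: 20 participants
block-randomized 1:1 in blocks of two; per-visit latent adherence
$p_{iw} = \mathrm{logit}^{-1}(\mu_{a(i),w} + b_i + \varepsilon_{iw})$ with
participant intercepts $b_i$ and visit-level noise on the logit scale
(matching the analysis model, rather than a beta-binomial alternative, so
that parameter recovery is well-posed); integer pill counts
$\mathrm{remaining} = \mathrm{round}(N_w (1 - p_{iw}))$ over dispensing
intervals of 14, 14 and 28 days; MEMS openings on each scheduled day with
probability $p_{iw}$ at a habitual time drawn uniformly in [07:00, 22:00]
plus Gaussian jitter; QIDS trajectories as baseline + week effects + arm
offsets + noise, rounded and clamped to [0, 27]; and withdrawals that
truncate all records from the withdrawal week.

Defaults, all recorded in the generated `truth` object:

* placebo adherence cells 90/79/66% at weeks 2/4/8; MPH cells offset on the
  logit scale by +0.06, −0.60 and −1.01 — the arm contrasts the trial's
  published default-prior fit reported — so the synthetic data reproduce the
  observed placebo-over-MPH direction.
* random-intercept SD 0.7 and residual SD 0.5 logit units: enough
  participant-level spread to be realistic for adherence data (a cell at 85%
  spans roughly 60–96% across participants) while keeping the logit-normal
  mean within a few points of the inverse-logit cell mean, so
  probability-scale summaries remain interpretable.
* MEMS jitter SD 1.5 h, so the ±6 h window is informative but rarely
  saturated.
* QIDS: baseline 17.8 ± 2.5, week effects around −7 to −9.5 points (−8.77 at
  week 8), small arm-by-week offsets, residual SD 2.2 — the published
  posterior medians of the exploratory outcome.
* four withdrawals among 20, at a week drawn from {2, 3, 4, 6}.

What the generator does **not** emulate: dose escalation at week 4,
visit-window jitter in the calendar dates, digit preference or other
human-recording artifacts in pill counts, curiosity-opening bursts in the
MEMS log, missing-not-at-random dropout tied to symptom severity, and any
covariate structure (age, sex, medication beliefs). Passing
parameter-recovery tests on these synthetic trials therefore demonstrates
that the analysis machinery is calibrated for the assumed generative
process; it cannot validate the published trial's specific posterior values,
which would require the original records.

## The Bayesian mixed model

For adherence outcomes the response is the logit of the percentage. Values
above 100 are clamped to 100 (counted and reported); exact 0/100 values are
moved off the boundary by adding half a pseudo-dose,
$p' = (pN + 0.5)/(N + 1)$ with $N$ the scheduled doses of the interval (a
fixed-ε clamp is available as an alternative policy). QIDS is modeled on its
raw scale.

The model is $y = X\beta + b_{\mathrm{participant}} + \varepsilon$ with
reference coding (placebo, earliest week), i.e. the intercept is the
reference cell, and:

* $\beta_j \sim N(m_j, s_j^2)$ — defaults $m_j = 0$ (intercept: the sample
  mean of the outcome) and $s_j = 2.5$, autoscaled by
  $s_j \times \mathrm{sd}(y)/\mathrm{sd}(x_j)$ (intercept:
  $\times\,\mathrm{sd}(y)$);
* $\sigma \sim \mathrm{Exponential}(1)$, rate divided by $\mathrm{sd}(y)$
  under autoscale;
* $\tau^2 \sim \mathrm{Gamma}(\text{shape} = 1, \text{scale} = 1)$ for the
  random-intercept variance.

The informative prior replaces the zero means with the reference-coded
transform of a pro-MPH adherence grid (96/90/82% vs 90/79/66% at weeks
2/4/8), sets every $s_j = 1$ and disables autoscaling. These are contracts on
the priors as stated, not an attempt to byte-match any particular regression
package's autoscale internals, which are version-dependent.

Sampling runs through JAGS (4 chains × 2000 iterations, first 1000 discarded
as warm-up, one RNG stream per chain derived from the seed). JAGS's `glm`
module is loaded so the linear structure is block-updated; without it the
intercept/random-effect geometry mixes too slowly to meet the convergence
contract at 2000 iterations. Gradient-based samplers would satisfy the same
contract; the requirement is on output quality (split R-hat at most 1.01 on
standard fits), not on the sampler family. Split R-hat is computed per
parameter by halving each chain; values below 1 — estimator noise when
between-chain variance is negligible — are floored at 1.000, and any value
above 1.05 raises a convergence warning on the fit.

Posterior summaries are medians with central 80% and 95% credible intervals;
estimated marginal means per arm × week are linear reads of the coefficient
draws (the reference cell *is* the intercept draw, a coding identity the
tests assert); Pr(MPH > placebo) at a week is the fraction of draws where
the MPH-minus-placebo cell difference is positive; and for QIDS the week-8
change-from-baseline difference between arms equals the corresponding
interaction draw. No multiplicity adjustment is applied across outcomes or
weeks, matching the analysis the package reproduces. Prior-only sampling —
the same model with every outcome masked — is used by the tests to verify
that the machinery reproduces the resolved prior moments.

## How the experiments are sized and judged

The test suite's calibration experiments, chosen to keep a full run inside a
few minutes on one CPU while leaving Monte-Carlo noise well below the
quantities checked:

* operating characteristics at 10,000 replicates (binomial SE at most 0.5
  points), compared cell by cell against the exact noncentral-t interim
  oracle and the quadrature oracle;
* parameter recovery at $n = 20$: 50 replications, each fixed effect's
  generating value inside its 95% credible interval in at least 90% of
  replications. Coverage is judged per parameter: a joint all-six-inside
  criterion conflates calibration with the dependence structure of the six
  intervals (six independent 95% intervals would be jointly right only about
  74% of the time) and is not what interval calibration means. Recovery runs
  generate trials without withdrawals, since the intention-to-treat
  zero-imputation is deliberately inconsistent with the latent adherence
  model and would contaminate truth recovery;
* precision at $n = 100$: 20 replications, mean absolute error of each fixed
  effect's posterior median at most 0.3 logit units;
* prior-sensitivity ordering: on a common dataset, the pro-MPH informative
  prior never lowers Pr(MPH > placebo) relative to the default prior.

Residual caveat: integer pill counts coarsen the response (a 14-dose
interval moves in steps of about 7 points, and the boundary shrink caps the
logit at about 3.37), which biases tightly-estimated within-participant week
contrasts by roughly 0.08 logit units at a 90% cell. This is a property of
analyzing percentages computed from small integer counts, not of the
sampler; it is visible in the recovery experiments and would apply equally
to real pill-count data.

## Known limitations

* The boundary recursion is written for general K-stage designs but
  validated only up to three stages, and only for symmetric two-sided
  designs reduced to one-sided spending; survival or binary endpoints are
  out of scope.
* The OC simulation covers pooled-variance t tests with Gaussian outcomes
  only (no Welch variant, no skewed outcomes).
* MEMS vendor binary formats are not parsed; the event log is consumed as a
  timestamp table.
* Bayes-factor model comparison is not implemented; the analysis reports
  posterior summaries and exceedance probabilities only.
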