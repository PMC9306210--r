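---
title: "Estimating the health effect of unemployment: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the health effect of unemployment: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalrd)
```

## The scientific problem

Unemployment and poor health are entangled in both directions: unemployment
may damage health, and people in poor health are more likely to become
unemployed ("health selection").  `causalrd` implements the estimation
machinery for cohort studies of this question with a binary outcome (poor
versus good self-rated health at follow-up), a binary labour-market
exposure (unemployed versus employed), and a set of categorical
confounders measured at baseline.  Three methodological axes are covered:

1. **How unemployment is measured** — self-reported accumulated
   unemployment over a three-year window, register-based accumulated
   unemployment days, or the current-status tick on a survey question,
   each optionally combined with a follow-up "censoring" policy that
   excludes participants with unemployment (or too little labour-market
   attachment) during follow-up.
2. **Which statistical method is used** — logistic regression odds
   ratios, G-computation, and three propensity-score weighting
   estimators of the marginal risk difference.
3. **Which confounders enter the model** — a 24-model sensitivity grid
   around a full (11-confounder) and a reduced (significant-confounder)
   adjustment set.

## Estimand and estimators

All risk-difference estimators target the marginal contrast
$E[Y(1)] - E[Y(0)]$: the change in the probability of poor health if
everyone were unemployed versus everyone employed.  With $Y_i$ the
outcome, $X_i$ the exposure and $PS_i = P(X_i = 1 \mid Z_i)$ the
propensity score estimated by logistic regression on the confounders
$Z_i$:

* **Standard IPW** (`rd_ipw`):
  $\frac{1}{n}\sum_i \left( \frac{Y_i X_i}{PS_i} - \frac{Y_i(1-X_i)}{1-PS_i} \right)$.
  Unbounded when scores are extreme; kept deliberately free of trimming
  so instability is visible rather than masked.
* **Augmented (normalised) IPW** (`rd_aug`): the same weighted sums with
  the weights normalised within each exposure arm, which bounds the
  estimate to $[-1, 1]$.
* **Doubly robust** (`rd_dr`): combines the weights with predictions
  $m_0, m_1$ from outcome models fit separately on the employed and the
  unemployed (same covariates as the propensity model) and evaluated at
  every participant's covariates.  Consistent when either the
  propensity model or the outcome models are correct.  The implemented
  statistic carries a $1/n$ normaliser: without it the sum scales with
  the sample size and cannot be a risk difference.
* **G-computation** (`rd_gcomp`): fit one logistic outcome model on
  exposure plus confounders (main effects by default), then average
  predictions with exposure forced to 1 and to 0 for everyone.
* **Logistic regression** (`or_logistic`): the conditional odds ratio
  for exposure with a 95% profile-likelihood interval.

Inference for the risk differences is by percentile bootstrap
(`bootstrap_estimate`): resample participants with replacement, re-run
the *entire* estimation (propensity fit, outcome fits, estimator) per
replicate, and take the 2.5% and 97.5% empirical percentiles.  The
bootstrap MSE is the mean squared deviation of replicate estimates from
the full-data point estimate; we centre on the full-data estimate rather
than the replicate mean because the quantity reported alongside the
intervals is the mean squared *error* of the estimator, and the two
definitions are compared algebraically in the test suite (MSE equals
replicate variance plus the squared deviation of the replicate mean
from the point estimate).

### Singular replicates

Resampling is unstratified, so a replicate can lose most (or all) of an
exposure group; stratified outcome fits then face constant outcomes or
perfect separation.  The logistic fitter raises machine-readable
conditions for both (`causalrd_degenerate_response_error`,
`causalrd_separation_error`, both subclasses of
`causalrd_singularity_error`), and the bootstrap skips and counts such
replicates per estimator instead of aborting: the reported `effective_B`
falls below the requested `B`.  When fewer than half the replicates
succeed the result is flagged unreliable; the pipeline additionally
suppresses reporting entirely when fewer unemployed participants remain
than a configurable threshold (default 30), which is the regime where a
doubly-robust analysis of a censored current-unemployment design stops
being reportable.

## The logistic core

`fit_logistic` is a self-contained Newton/IRLS maximiser (compiled, with
step-halving) rather than a wrapper around a host routine, because the
bootstrap needs an explicit, classed singularity signal rather than a
silent non-convergence.  Numerical choices:

* Convergence: maximum absolute score below `1e-8`, or relative
  log-likelihood change below `1e-10`, within 50 iterations.
  G-computation tightens these to `1e-12`/`1e-15` (200 iterations) so
  that standardised means inherit near-exact MLE precision; the
  saturated-model equivalence with direct standardisation holds to
  `1e-12` in the tests.
* Intercept-only designs use the closed-form MLE
  $\hat\beta_0 = \mathrm{logit}(\bar y)$, which makes the collapse
  identities (all estimators equal the crude risk difference when no
  covariates are used) exact to machine precision.
* Separation is declared when fitted probabilities reach within `1e-7`
  of 0 or 1 at the optimum: the solver halts with linear predictors
  beyond $\pm 16$ only when a direction of divergence exists, which
  cannot occur for non-separated designs built from categorical
  covariates of this codebook.  The offending column (largest
  standardised coefficient) is named in the condition.
* Profile-likelihood intervals solve
  $2\{\ell(\hat\beta) - \ell_p(\beta_j)\} = \chi^2_{1,0.95}$ by monotone
  bracketing in Wald-SE steps and root refinement, re-maximising all
  other coefficients at each evaluation; a profile that has not reached
  the cut-off within 100 standard errors is reported as an open bound.
  No penalisation or small-sample correction is applied anywhere: plain
  maximum likelihood is the method under study, and its instabilities
  are surfaced, not patched.

## Exposure derivation

The three measurement modes consume per-participant labour-history
records:

* *Self-reported long-term*: unemployed with at least 6 months of
  self-reported unemployment over the 3 retrospective years; employed
  with zero unemployment months and at least 18 months of attachment
  (full-time, part-time 20–39 h, or labour-market measure); otherwise
  excluded with a reason code.
* *Register long-term*: unemployed with at least 182 registered
  unemployment days over the three register years (182 = ⌈365/2⌉,
  because the register counts days while the rule is stated in months);
  employed with zero registered days plus the same attachment rule.
* *Current*: classified from the single current-status tick; studies,
  other education, casual work, sick leave, parental leave and "other"
  are outside the labour market and excluded.

Censoring flags (never relabels) participants with any follow-up
unemployment or under 18 follow-up attachment months; flagged rows are
removed before estimation.  Whole months are assumed throughout (the
source instruments collect whole months), and follow-up attachment is
measured with the same status vocabulary as the baseline window.

## The synthetic cohort generator

Real cohorts of this design are not shareable, so the package carries a
first-class generator (`generator_config`, `generate_cohort`) whose
defaults define the study conditions used by the tests:

* n = 805 participants; 11 independent categorical confounders with the
  study population's marginal frequencies (23% poor previous health,
  27% single, 42% blue-collar, …).
* A logistic exposure model targeting 22% unemployment, with
  health selection built in: poor previous health carries a log-odds
  coefficient of 0.9 on unemployment.
* A logistic outcome model targeting 36% poor health, with a
  conditional exposure odds ratio of 1.9 and a previous-health odds
  ratio of 4.0 — magnitudes anchored to the full-model analysis this
  machinery is built for; they are calibration anchors, not claims of
  reproducing any particular cohort.
* Nonzero coefficients sit only on previous health, education, marital
  status and occupation, so those four variables are the generating
  signal that the reduced-model selection should recover.

Intercepts are calibrated by exact enumeration over the joint
distribution of the coefficient-bearing confounders (`uniroot` on the
marginal prevalence equation), so the configured prevalences hold by
construction rather than by tuning.  `true_marginal_rd` evaluates the
generator's true marginal risk difference by Monte-Carlo
standardisation (default $10^6$ draws, with its standard error); under
the defaults it is ≈ 0.136, squarely in the range the risk-difference
estimators produce at these prevalences.

Labour histories (`generate_labour_history`) are generated so that one
self-reported month corresponds to 30.4 register days, making the two
long-term modes classify identically by construction; a discordance
parameter injects short register-only spells (the mechanism by which
register data capture between-jobs unemployment that self-reports
miss), which tilts the register mode toward more unemployed.  Current
status ticks "unemployed" for only ~35% of the long-term unemployed,
reproducing the large gap between current (~8%) and accumulated
(~22%) unemployment prevalence.

What the generator does **not** emulate: dependence among confounders
(optional Gaussian-copula couplings exist but default to off, since
only marginals are available to calibrate against), attrition,
measurement error in the confounders, and longitudinal health
trajectories.  Passing tests therefore demonstrate correctness of the
estimation machinery under the assumed data-generating structure, not
fidelity to any real cohort.

## The model ledger

`full_model_spec` (model 1, all 11 confounders) and
`select_significant` (model 13: confounders with any non-reference
level whose profile-likelihood interval excludes OR = 1 at 5%) anchor
`build_ledger`'s grid: models 2–12 drop each confounder from the full
model, 14–17 drop each member of the reduced model, 18–24 add back each
excluded confounder.  Selection is at the variable level — a
categorical variable is kept if *any* of its levels is significant, and
enters or leaves with all its indicator columns — and profile-likelihood
intervals are used for the selection decision, consistent with the
interval method reported for the odds ratios.  `run_ledger` shares one
bootstrap resample-index matrix across all models so that between-model
deviations reflect the adjustment sets, not bootstrap noise
(independent resamples are available via `share_resamples = FALSE`).

## Problem sizes used in validation

The test suite validates the machinery at the following scales, chosen
as the package's own study design: formula-oracle equivalence on 1,000
random micro-instances (n ≤ 20, tolerance 1e-12); double-robustness and
parameter-recovery simulations at n = 2000 × 500 and n = 5000 × 200
replicates; and bootstrap coverage on 500 simulated cohorts of n = 805
with B = 500 replicates each, analysed with the four signal covariates
(a correctly specified model, since the remaining seven confounders
carry null generating coefficients).  B = 500 is a deliberate
scale-down of the 10,000-replicate default used for a single
production analysis; percentile endpoints are slightly noisier but the
coverage assessment is driven by the number of simulated cohorts.
Known limitations: standard IPW can exceed the logical range of a risk
difference under extreme scores (documented and tested, not clipped),
the bootstrap assumes i.i.d. sampling of participants, and the
current-unemployment mode with censoring is computable but rarely
reportable — by design, the package flags rather than fixes this.
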