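---
title: "Modelling probability learning and risk weighting in a two-option reward task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling probability learning and risk weighting in a two-option reward task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banditfit)
library(dplyr)
```

## The task

`banditfit` models behaviour in a 60-trial two-option probabilistic reward
task. On each trial two stimuli are shown, each displaying a reward
magnitude; one stimulus carries a 0.75 probability of being rewarded, the
other 0.25, and the subject must learn which through experience. Exactly one
stimulus is rewarded on every trial, and a response earns the chosen
stimulus's magnitude only if that stimulus was the rewarded one. Magnitudes
are complementary — one option shows an integer R drawn uniformly from
1–99, the other 100 − R — so magnitude information alone never identifies
the better option. The probability contingency is re-randomized every 20
trials, giving three blocks. To discourage perseveration, an option chosen
on two consecutive trials has its magnitude on the next trial redrawn from
the lower half of the range (1–49).

The "correct" choice on a trial is the option with the higher true expected
value: true probability × displayed magnitude. Because the high-probability
option often shows a small magnitude, maximizing expected value requires
integrating both quantities; an agent that over-trusts the learned
probability (risk-averse) or ignores it (risk-seeking) loses points.

`task_config()`, `build_schedule()`, `apply_magnitude_adjustment()` and
`resolve_trial()` implement this structure; `simulate_agent()` plays any of
the models below through it.

## The eight models

All models learn a predicted reward probability $p_t$ for one stimulus
(the other's is $1 - p_t$), initialized at 0.5, updated after each choice
from the reward indicator $r_t \in \{0, 1\}$ of the chosen stimulus:

$$p_{t+1} = p_t + \alpha_t \, \delta_t, \qquad \delta_t = r_t - p_t .$$

The variants differ in the learning rate $\alpha_t$:

* **s1** — constant $\alpha$ (Rescorla–Wagner).
* **s2** — $\alpha_+$ for positive and $\alpha_-$ for negative prediction
  errors.
* **d1** — Pearce–Hall: an associability $S_t$, a running average of
  absolute prediction errors, gates the rate,
  $S_{t+1} = (1-\mu) S_t + \mu\,|\delta_t|$ and
  $\alpha_{t+1} = \kappa\,S_{t+1}$.
* **d2** — one rate $\alpha_1$ for the first half of trials and another
  $\alpha_2$ for the second half.

Each has a weighted variant (s1w, s2w, d1w, d2w) that passes the learned
probability through a linear probability-weighting transform before it is
combined with magnitude:

$$F(p, \gamma) = \max\!\big[\min\!\big(\gamma (p - 0.5) + 0.5,\; 1\big),\, 0\big],$$

so $\gamma = 1$ is risk-neutral (identity), $\gamma > 1$ compresses
probabilities toward 0/1 (risk-aversive) and $\gamma < 1$ flattens them
toward 0.5 (risk-seeking). Expected values are
$Q_t(\cdot) = \text{magnitude} \times F(p_t(\cdot), \gamma)$ (with
$F$ the identity in the unweighted models), and choices follow the
sigmoidal rule

$$P(\text{choose } A) = \frac{1}{1 + e^{-\beta\,(Q_t(A) - Q_t(B))}},$$

with inverse temperature $\beta \ge 0$. On the 0–100 point scale typical
$\beta$ values are small; the prior below has mean 0.14.

### Numerical and structural choices

Several aspects of the update are under-determined by the equations alone;
the package fixes them as follows, each switchable where noted.

* **Update source.** Only the chosen stimulus's outcome drives the update
  (the update rule conditions on the choice), even though feedback reveals
  the rewarded stimulus on every trial. For symmetric rules this is
  equivalent to always updating from the full outcome; for s2 (sign-split
  rates) it matters.
* **Block resets.** Because the contingency is re-randomized at each block
  boundary, the learner state ($p$, and $S$ for dynamic models) is
  re-initialized to 0.5 (and $S_0$) at block starts by default
  (`reset_blocks = FALSE` keeps state across blocks).
* **Pearce–Hall ordering and initial associability.** The associability is
  refreshed with the current $|\delta_t|$ before the value update, so the
  rate applied on trial $t$ is $\kappa S_{t+1}$, matching the $t+1$
  indexing of the rate equation; `assoc_first = FALSE` gives the other
  ordering. $S_0 = 1$ by convention, and the effective rate is clamped to
  $[0, 1]$ so $p$ cannot leave the unit interval.
* **No-response trials** contribute no likelihood and trigger no update.
* **Magnitude adjustment amount.** The repeat-choice reduction is a uniform
  redraw from the lower half of the magnitude range {1,…,49}: it guarantees
  a reduction in expectation and preserves complementarity. The repeat
  counter resets at block boundaries and is broken by a no-response trial.
* **Overflow safety.** Choice log-probabilities are computed as
  $-\log(1 + e^{-x})$ with the sign folded in, so extreme
  $\beta \, \Delta Q$ cannot overflow.

## Fitting: MAP estimation with Laplace model evidence

`fit_map()` maximizes the per-subject log posterior: the trial-wise
log-likelihood plus log prior densities. The default priors are
Beta(4.6, 50) for all learning rates, Gamma(shape 1.9, scale 1.0) for
$\gamma$, Gamma(shape 2.8, scale 0.05) for $\beta$, and the flat
Beta(1, 1) for the Pearce–Hall $\mu$ and $\kappa$. The gamma priors are
parameterized shape–scale, so the $\beta$ prior has mean 0.14 — a sensible
inverse temperature when expected values span 0–100. A less constrained
Beta(2, 2) learning-rate set is available via `default_priors("beta22")`
for sensitivity analyses.

Optimization is multi-start Nelder–Mead simplex search on the raw,
constrained parameters, with the log posterior returning $-\infty$ outside
any prior's support. Searching the raw space (rather than a transformed
one) keeps the MAP where the prior puts it; a log- or logit-transformed
search would relocate the mode by the Jacobian. Starts are drawn from the
priors, which covers the support with sensible mass; the default is 100
restarts, and restart draws are nested so that increasing the count can
only improve the best optimum found. Fits are bit-reproducible given a
seed.

Model evidence is the Laplace approximation at the MAP:
$\log Z \approx \log p(\theta^\*) + \tfrac{k}{2}\log 2\pi -
\tfrac12 \log \det H$, with $H$ the Hessian of the negative log posterior
computed by central finite differences. The step size matters more than
usual here: the likelihood is only piecewise smooth (the weighting
transform clips at 0 and 1, s2 switches rates at zero prediction error,
the Pearce–Hall rate is clamped), and second differences taken at
infinitesimal steps measure those kinks — which scale as $1/h$ — rather
than the posterior's curvature, which can deflate a model's evidence by
several nats. Each coordinate's step is therefore calibrated so the
negative log posterior rises by about half a nat at $\theta \pm h$: the
curvature of the posterior bulk at its own scale, which is the quantity
the Gaussian approximation integrates (exact for a quadratic at any step).
One retry at ten times the calibrated steps handles nearly-flat $\beta$
directions. A mode can sit on a support boundary — the Pearce–Hall $\mu$, for
instance, is pushed to 0 when the data carry no associability dynamics —
in which case a central step would leave the support; such coordinates fall
back to one-sided differences into the interior, so the reported evidence
reflects the curvature on the feasible side. One-sided cross terms are only
first-order accurate and can leave the matrix indefinite; if so, the
boundary coordinates are decoupled (their cross terms zeroed, their interior
diagonal curvature kept), which in Monte Carlo checks errs by at most a
couple of nats, on the conservative side. If the Hessian still is not
finite and positive definite the evidence is
reported missing and the fit flagged (`hessian_ok = FALSE`). The
determinant term penalizes extra parameters automatically, so comparing
mean evidence across subjects (`compare_models()`) trades fit against
complexity; exact ties break toward the smaller model.

## The synthetic cohort generator

Real choice data for this design are not redistributable, so
`generate_cohort()` builds populations with the structure the analysis
stage is meant to detect: four cells (male/female × low/high perceived
stress, classified by a Perceived Stress Scale score of 19 or above). The
defaults — chosen once, as a plausible qualitative pattern, not as
estimates of any particular dataset — are:

* $\gamma$: mean 1.6 for high-stress females vs 1.1 for high-stress males
  (SD 0.3); both low-stress groups 1.2. Higher $\gamma$ (stronger risk
  aversion) degrades expected-value performance, so this induces a sex gap
  in accuracy under high stress that is *caused by* probability weighting.
* $\alpha$: mean 0.20 for low-stress females vs 0.10 for low-stress males
  (SD 0.05); high-stress groups 0.15.
* $\beta$: mean 0.14, SD 0.05, shared across groups (the prior mean).
* PSS scores: discretized normals, low group 14.89 ± 3.06 and high group
  23.17 ± 3.79, truncated to each group's side of the threshold.

The generative model is s1w by default (s1 selectable for model-recovery
studies). What the generator deliberately does **not** emulate: no-response
trials (simulated agents always respond), reaction times, within-session
drift or fatigue, demographic covariates, and any correlation between PSS
and the generative parameters beyond the group means. Tests passing on
these cohorts therefore validate the machinery — schedule statistics,
estimator consistency, selection behaviour, analysis calibration — not any
empirical claim about human sex or stress differences.

## The analysis stage

* `score_correct_choices()` computes the proportion of higher-expected-value
  choices per subject, overall and per block. Trials where the two expected
  values tie exactly (possible at R = 25 vs 75 under 0.75/0.25) are
  excluded from the denominator — the conservative choice — as are
  no-response trials.
* `group_contrasts()` runs the sex × stress two-way ANOVA with type-II sums
  of squares (cohorts are near-balanced by construction; the type matters
  little but is stated), uncorrected pairwise sex contrasts within stress
  level, and a repeated-measures variant with block as a within-subject
  factor.
* `sex_difference_glm()` estimates the unstandardized sex coefficient
  (male = 1, female = 0) on proportion correct among high-stress subjects,
  overall and per block, with and without each fitted parameter as a
  covariate; the attenuation statistic $1 - b_{adj}/b_{unadj}$ quantifies
  how much of the gap a covariate absorbs.
* `parameter_performance_regression()` regresses accuracy on each fitted
  parameter within sex.
* `validate_model_regression()` checks, per subject, that choices track
  both the magnitude difference and the model's weighted-probability
  difference (logistic regression), then tests the coefficient populations
  against zero — a two-stage summary-statistics stand-in for a full
  random-effects mixed model, which is out of scope; subjects with
  separated regressions are excluded from the group test.

## Problem sizes used in the test suite

The validation suite exercises the pipeline at sizes chosen to make its
statistical checks informative while remaining desk-scale: schedule
statistics at 10,000 trials; likelihood oracle checks on 20 random
model/data pairs; optimizer-vs-grid checks against a 200³ grid on three
instances; parameter recovery on a 64-subject cohort at 100 restarts plus
100 replicate single-subject fits; model recovery over 20 replicate
40-subject cohorts at 20 restarts (the winning-model margins are a few
tenths of a nat, so mean-evidence selection needs cohorts of roughly this
size to be stable); ANOVA type-I calibration over 200 replicate
32-subject null cohorts. Each of these sizes is stated in the corresponding
test.

## Known limitations

* The Laplace evidence assumes a locally Gaussian posterior; for strongly
  skewed posteriors (small $\beta$, short sessions) it is approximate, and
  the Beta–Bernoulli oracle test bounds the error only in a conjugate toy.
* Parameters are fit per subject with fixed priors; there is no
  hierarchical pooling, MCMC posterior, or uncertainty on the MAP point
  estimates beyond the Hessian.
* The per-subject + group-level validation regression approximates, but is
  not, a generalized linear mixed model.
* With 60 trials, $\gamma$ and $\beta$ are partially confounded (both
  sharpen choice); recovery of $\gamma$ is rank-accurate rather than
  unbiased, and the priors shrink extreme subjects.
* Nested weighted variants are nearly indistinguishable on data generated
  from the constant-rate weighted model: under the default priors the
  exact (Monte Carlo) evidence gap between that model and its
  asymmetric-rate variant is below 0.1 nat per subject at 60 trials, so
  mean-evidence selection among the nested weighted models approaches a
  coin flip at cohort sizes of a few dozen. Model-selection wins between
  such close variants should not be over-read; selection against the
  unweighted and Pearce–Hall families is robust.
* The task simulator does not model reaction times, stimulus identity
  effects, or left/right position (options are latent identities).
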