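---
title: "Modified-loss boosting for individualized treatment rules: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modified-loss boosting for individualized treatment rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itrboost)
```

## The estimation problem

`itrboost` targets the treatment-contrast function of a two-arm trial. With
potential outcomes Y(1), Y(−1), arms coded A ∈ {+1, −1}, and biomarkers X,
we work under

$$E(Y \mid A, X) = H(X) + Z(X)\,A,$$

where Z(X) = ½[E(Y|A=1,X) − E(Y|A=−1,X)]. The individualized treatment rule
(ITR) is sign(Z(X)): treat exactly the patients for whom the contrast is
favourable. The package estimates a monotone transform f(X) of Z(X) by
minimizing one of two composite losses built from a per-patient kernel
M(y, v):

* **A-learning**: v = c·f(X) with c = (A+1)/2 − π(X). Centring the treatment
  indicator at the propensity makes the main effect H(X) drop out of the
  population minimizer, so H is never estimated.
* **Weight-learning**: v = A·f(X), each patient weighted by
  w = 1/[Aπ(X) + (1−A)/2], i.e. 1/π on the treated arm and 1/(1−π) on
  control — classical inverse-propensity weighting.

Both are Fisher-consistent for sign(Z) when M(y, v) is convex in v and its
derivative at v = 0 is monotone in y. The package verifies both conditions
numerically in its test suite rather than proving them; the empirical
stand-in is the recovery accuracy of the true benefit subgroup on simulated
trials where Z is known.

Assumptions worth stating plainly: a randomized (or correctly modelled
propensity) two-arm assignment; outcomes missing only completely at random
(rows with missing outcome or arm are dropped with a count); for survival,
independent censoring and proportional hazards within the horizon τ.

## Loss kernels and their derivatives

| Endpoint | M(y, v) | Link of f |
|---|---|---|
| continuous | (v − y)² | identity |
| binary | log(1 + eᵛ) − y·v | logit |
| survival | −δ·1(Z ≤ τ)·(v − log Ê[eᵛ I(Z ≥ u)]) at u = Z | log-hazard |

Two typographic ambiguities in the printed literature on this family had to
be resolved:

* **Binary kernel dialect.** A form like −[yv − log(1 + e^{−v})] is not
  simultaneously convex in v and monotone at 0; we use the standard
  Bernoulli negative log-likelihood with logit link, which is. Because the
  kernel's argument is c·f or A·f, the sign convention of f is what the
  benefit rule keys on, and that is fixed per endpoint (below).
* **Weight-learning factor.** The propensity factor is applied as a
  *divisor* (a weight), not a multiplier. As a multiplier it would
  down-weight the very arm it should reweight and the randomized-trial
  identity L_W = 2·mean M at π = 0.5 — which the tests assert exactly —
  would fail.

The survival kernel is the negative Breslow partial-likelihood
contribution: the risk-set expectation Ê[eᵛ I(Z ≥ u)] is the unweighted
sample mean over all patients, tied event times share a denominator, and
only events at or before τ count. τ defaults to the largest observed event
time. Whether inverse-propensity weights should also enter the risk-set
mean is genuinely underdetermined; we default to outer-only weighting
(weights multiply each patient's kernel contribution, not the risk sets)
and expose `inner_weights` in `loss_config()` for the alternative.

Boosting needs per-patient first and second derivatives. For the separable
continuous and binary losses these are chain-rule one-liners; for survival
the gradient is the exact partial-likelihood derivative including risk-set
cross terms, computed in O(N log N) by cumulative sums over time-sorted
patients, and the Hessian is the usual diagonal approximation
Σₖ wₖ pₖ(1 − pₖ) over event times with pₖ the risk-set softmax weight.
Derivatives are returned on the summed-loss scale (N × the mean loss);
the constant is absorbed by the learning rate and L2 penalty.
`loss_gradient()` is checked against central finite differences of
`composite_loss()` for all six endpoint × loss combinations, and
`composite_loss()` itself against a naive double-loop risk-set oracle.

Numerical choices: all logistic and risk-set terms use stable
log-sum-exp/`log1p` forms (scores are centred by their maximum before
exponentiation); the Hessian is floored at 1e−16 so a boosting step is
always defined; the boosting base score is fixed at 0 because the losses
are defined around f = 0 (an engine default of 0.5 would silently bias the
first rounds).

## Fitting, the ITR, and importance

`fit_subgroup_model()` passes the analytic derivatives to xgboost as a
custom objective and records the composite loss per round. The default
`boosting_params()` — learning rate 0.01, depth-1 stumps, λ = 5, 300
rounds, histogram trees — are the tutorial configuration this family of
models is usually demonstrated with: stumps plus strong L2 keep the
contrast surface additive and conservative, which suits the low
signal-to-noise of treatment-effect estimation. Early stopping is off by
default (a fixed budget keeps runs deterministic and comparable); all
fitting is single-threaded and seeded, so identical inputs give
bit-identical models.

The treatment recommendation thresholds f̂ at 0. Two conventions are fixed
here rather than left implicit:

* **Benefit direction.** For continuous and binary endpoints larger
  outcomes are better, so benefit is f̂ > 0. The survival score lives on
  the log-hazard scale, so benefit is f̂ < 0. Both are overridable
  (`benefit_direction`), since "higher is better" is a property of the
  outcome definition, not of the algorithm.
* **Ties.** f̂ = 0 means no evidence of benefit; the rule returns −1
  (control). The simulator uses the same convention for Z = 0, so generator
  and estimator can never disagree about the truth label.

Importance ranking aggregates xgboost's gain over the one-hot columns of
each categorical biomarker, normalizes to sum 1, and ranks densely by
descending gain; split frequency is reported alongside but never used for
ranking. An ensemble with no splits raises an explicit error rather than
returning an empty table.

## Cutoffs, subgroup tables, association diagnostics

Cutoff evaluation is deliberately restricted to user-supplied candidates
(the companion-diagnostic setting); there is no continuum-wide search and
therefore no selection-bias correction. Conventions, each of which the
tests pin down exactly:

* "Biomarker-positive" strictly meets the direction: x > c under `">"`;
  values equal to the cutoff are negative. Flipping the direction swaps the
  classification and leaves the Fisher p unchanged.
* Fisher's exact p is the two-sided probability-mass definition; it and
  Cohen's kappa are checked against full hypergeometric enumeration over
  all 2×2 tables with margins ≤ 12.
* Selection maximizes Youden/kappa or minimizes the association p-value;
  p-value ties break toward the larger biomarker-positive group
  (enrichment-friendly). Tests are two-sided; no multiplicity adjustment is
  applied across candidates, but the candidate count is always reported.

The arm × biomarker-group table fits, per group, the endpoint-appropriate
two-arm model (linear / logistic / Cox) for the within-group contrast, and
a single joint model with a group × arm term for the interaction test —
Wald on the interaction coefficient for two groups, likelihood-ratio
against the no-interaction model for more. Regression adjustment (not
stratification) is used when adjusters are supplied. Kaplan–Meier medians
use log(−log) confidence intervals; groups with an arm below `min_n = 2`
are summarized but excluded from model-based contrasts.

The ROC sweep collapses tied scores into diagonal segments, which makes the
trapezoidal AUC equal the Mann–Whitney U statistic with ties counted ½ (the
tests assert this to 1e−12); `direction = "auto"` orients the curve so
AUC ≥ 0.5. Smooth curves use penalized cubic regression splines
(`mgcv::gam`, GCV-selected smoothing, user-chosen basis dimension k,
reduced with a warning when the distinct-value support is smaller) on the
endpoint's link scale; the survival smooth is of martingale residuals from
a null Cox model, the standard functional-form diagnostic, because no
direct "log-hazard smooth" is defined without a model. The treatment
contrast is the difference of per-arm smooths with a band from the
root-sum-of-squares of the two standard errors; optional adjusters enter
additively and linearly. Every plotting function draws numbers the
computation already returned.

## What the simulator emulates — and what it does not

`simulate_trial()` generates iid standard-normal biomarkers (optionally
uniform categoricals), Bernoulli(π) assignment, and outcomes from
H(X) + Z(X)·A on the natural scale: Gaussian noise (sd 1 by default) for
continuous, logit for binary, exponential event times with log-hazard
H + Z·A and a baseline rate of 0.1 for survival. Censoring is independent
exponential with its rate solved by `uniroot` so the expected censored
fraction hits the target (0.3 by default, a typical oncology-trial figure);
the calibration is checked at n = 10,000 to ±0.02. Effect forms are
serializable specs (linear, threshold, constant), so every test states its
own truth.

The demonstration dataset (`tutorial_fixture()`, 600 patients, ten
biomarkers) makes x1 both prognostic and predictive with an effective
threshold at 0.5, so the candidate-cutoff walkthrough lands on 0.5 by
computation, not by fiat. It is labelled synthetic everywhere; it emulates
the *shape* of a tutorial trial, not any real rows.

Passing tests on these simulations show the machinery is correct under
independence, correctly specified generative links, and honest
randomization. They do not show robustness to correlated biomarker panels,
informative censoring, propensity misspecification, or non-additive
H — all of which real trials have. The optional exchangeable-correlation
and categorical features widen the net only slightly.

## Problem sizes and runtime posture

The test suite runs simulations at the sizes the claims are stated for:
N = 50–120 for the derivative and loss-identity oracles, N = 2000 for
subgroup-recovery accuracy (≥ 0.90 continuous, ≥ 0.80 binary/survival),
20 seeded replicates at N = 400 for the importance top-rank rate, 100
replicates at N = 800 for interaction power/size, N = 1000 for
contrast-curve recovery (within 0.25 of the true 2x on the central 80%
grid), and n = 10,000–50,000 spot checks of the generator's calibration.
These sizes were chosen as the smallest at which the Monte-Carlo error is
clearly below the stated margins.

## Known limitations

* Two arms only; no interval censoring, competing risks, or time-varying
  covariates; Breslow (not Efron) ties.
* No doubly-robust augmentation of the losses and no cross-fitted
  inference on the value of the fitted rule: the ITR is a point estimate.
* Cutoff selection reports no selection-adjusted inference; its p-values
  are exploratory.
* The survival contrast smooth (difference of per-arm martingale-residual
  smooths) is a diagnostic, not an estimate of a hazard ratio curve.
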