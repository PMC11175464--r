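---
title: "Surprise-minimization arbitration: models, simulation conditions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surprise-minimization arbitration: models, simulation conditions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surprisemin)
```

## The task and what the generator emulates

The multiple-bandits task couples two two-armed bandits: on every trial the
agent makes two decisions and receives two color-coded outcomes between 1
and 99 points, without being told which decision produced which outcome.
For each decision the two candidate outcomes are exactly anti-correlated
(`P` and `100 − P` points), and `P` drifts as a bounded Gaussian random
walk. The synthetic-task generator (`task_config()`, `generate_task()`)
reproduces the study conditions directly: 3 blocks of 100 trials, walk step
SD 15 points on [1, 99], the first walk value uniform over the integer
range, an independent walk per decision, win/loss threshold at 50 points,
and a randomized (hidden) decision-to-color mapping plus a per-trial
outcome presentation order. The presentation order only tags events for the
EEG stage; it never enters the model computations, because the evidence
update sums over both outcomes and is order-invariant.

What the generator does *not* emulate: reaction times, stimulus positions,
instruction or training effects, and any within-session non-stationarity of
real participants (fatigue, attention lapses). Passing tests on synthetic
agents therefore demonstrate that the algorithms are implemented correctly
and that the statistical machinery behaves as designed — not that human
data will show the same effect sizes.

### Walk boundary handling

The boundary behavior of the outcome walk is the one genuinely open design
choice in the task. We compared candidate schemes against the task's
outcome-stability property — outcomes should stay on one side of the
win/loss threshold for about 5.7 trials on average:

| scheme (at SD 15) | mean same-side run length |
|---|---|
| step negation ("bounce") | **5.63** |
| truncated-step resampling | 6.81 |
| reflection off the bound | 7.67 |
| clipping at the bound | 8.86 |

Only step negation — when a Gaussian step would leave [1, 99], apply it in
the opposite direction — reproduces the stability statistic, so it is the
default `bounds_scheme`; reflection and clipping remain available. The
intuition: negation re-injects outward-bound steps toward the center, which
concentrates the stationary distribution around the threshold and raises
the crossing rate relative to reflection (which leaves the stationary
distribution nearly uniform). Walk values are rounded to integer points
after the boundary rule, matching the displayed 1–99 point outcomes; exact
ties at 50 are classified as losses (a win is strictly above threshold),
which affects about 1% of trials and is logged by the dichotomization
helpers.

## The model set

`model_spec()` defines five candidates. The surprise-minimization model
runs two temporal-difference policies in parallel, one per candidate
mapping, each with counterfactual updating of the unchosen option
(subtracting the scaled prediction error, which the anti-correlated payoff
structure justifies; learning-rate-based decay and a free decay parameter
are available as `counterfactual_mode` variants). The policies emit
surprise — the absolute prediction error, read as negative model evidence —
and the arbitration stage converts the *difference* of the surprises the
two policies attribute to the same outcome into an evidence signal. Because
the two policies assign the same outcome to different decisions, this
comparison necessarily crosses decisions:
`evidence(o1) = surprise_incorrect(d2) − surprise_correct(d1)` and
symmetrically for `o2`. Evidence accumulates at the assignment rate into an
unbounded log-odds state whose inverse logit weights the correct policy's
values in a softmax choice rule with a perseveration bonus.

The within-trial order is fixed: choice probabilities from current values
and weight, then both actions, then both outcomes, then prediction errors
against pre-update values, then value updates, then surprise and evidence,
then the arbitration update for the next trial. Values and the arbitration
state reset to zero at every block boundary (the mapping re-randomizes
between blocks), and the perseveration indicator has no previous action on
a block's first trial.

The fixed-weight variants preset the assignment rate to zero and hold the
weight at 0.9 (correct), 0.1 (incorrect), or 0.5 (random). For the
single-policy *validation simulations* the weight is overridden to exactly
1 or 0 (`fixed_weight` argument), which makes the model provably identical
to a single TD learner on the relevant (resp. irrelevant) outcomes — one of
the exact equivalences the test suite asserts, alongside the equivalence of
the zero-assignment-rate model with the random-policy model. The fifth
candidate learns a single value per joint action (2 × 2 combinations) from
the summed centered reward, with perseveration applied to the full joint
action.

## Parameters, priors, and fitting

| parameter | meaning | bounds | prior |
|---|---|---|---|
| alpha | learning rate (shared across policies) | [0, 1] | Beta(1.2, 1.2) |
| beta | softmax inverse temperature | [0, 20] | Gamma(2, 1), truncated |
| rho | perseveration bonus (utility units) | [−5, 5] | Normal(0, 1), truncated |
| epsilon | assignment rate for evidence accumulation | [0, 1] | Beta(1.2, 1.2) |
| decay | optional unchosen-option decay | [0, 1] | Beta(1.2, 1.2) |

Truncated priors are renormalized over their bounds. MAP estimation
(`fit_map()`) maximizes the log posterior with bounded L-BFGS-B from
prior-drawn restarts (10 by default); bounds are shrunk inward by a 1e-4
relative margin because the Beta(1.2, 1.2) and Gamma(2, 1) densities vanish
at the boundary. The likelihood is evaluated by a compiled trial loop with
a max-subtracted softmax and an inverse logit clamped at |x| = 700, so the
unbounded evidence state cannot overflow; the same engine runs generatively
and in likelihood mode, which makes replayed latents exactly equal to
simulated ones.

Information criteria use `n` = number of modeled choices (two per trial),
since the likelihood is a product over decisions; this convention is
applied uniformly, including to the joint-action model. Group-level model
selection treats `−BIC/2` as the log model evidence per participant
(`−AIC/2` is available as a switch), feeds it to a variational Dirichlet
random-effects scheme (uninformative concentration 1 per model, tolerance
1e-6), and estimates exceedance probabilities from 10^5 Dirichlet samples.

### Identifiability of the model set

Two degeneracies are structural, not numerical. At `beta → 0` every
candidate model produces the uniform policy, so their likelihoods coincide
exactly and information criteria select the smaller parameter count by
construction. At `epsilon → 0` the surprise-minimization model *is* the
random-policy model. Model recovery from unrestricted prior draws therefore
mixes discrimination with tie-breaking; the package's recovery harness
accepts a `params_fun` so the confusion matrix can be estimated on the
identifiable regime (the acceptance checks use `beta ≥ 1`, `epsilon ≥
0.05`), while the default remains unrestricted prior draws. The
perseveration parameter is only weakly identified at 300 trials and its
recovery is reported without a hard threshold.

## Behavioral analyses

The stay/switch table codes, for each decision from the second trial of a
block on, whether the action was repeated, and the previous trial's two
outcomes (dichotomized to ±1) as relevant or irrelevant under the true
mapping — so every outcome predicts both upcoming actions, once in each
role. The primary estimator is the two-stage summary-statistics approach:
per-participant logistic regressions (`stay ~ relevant * irrelevant`),
then one-sample t-tests of the coefficients across participants. A pooled
logistic mixed model (random intercept) is available as `mode = "mixed"`;
with per-participant fits specified as the reference procedure, the
two-stage mode is primary and the pooled mode is clearly labeled as a
variant. Deterministic agents (high inverse temperature) separate their
per-participant fits; those fall back to a weakly penalized MAP logistic
fit (Gaussian prior, SD 2.5 on slopes) and are flagged rather than
silently dropped.

One empirical subtlety the tests respect: for a single-policy agent the
non-controlling outcome's stay coefficient is not exactly zero. Received
outcomes depend on the agent's own actions, which induces a small
mechanical correlation (on the order of 0.03 in the logistic coefficient).
The qualitative single-policy pattern is therefore asserted as dominance —
a large positive effect of the controlling outcome, a near-zero effect of
the other — rather than as a strict null.

The implicit credit-assignment score is the mixed-outcome contrast: the
stay probability after a relevant win paired with an irrelevant loss minus
the reverse cell, compared across participants by a Wilcoxon signed-rank
test. The signed-rank machinery reports the normal-approximation Z with
tie correction and no continuity correction; at complete separation of
*n* pairs the statistic is `(n(n+1)/4)/sqrt(n(n+1)(2n+1)/24)`, which for
1000 simulation runs is 27.39 — the ceiling against which the surprise
separation of the two policies is checked. Chance-level tests compare the
proportion of wins (and transfer accuracy, consumed as per-participant
proportions only) against 0.5 with the same machinery.

The choice-prediction regression uses pre-choice latents at trial *t* (the
decision values `V(a1) − V(a2)` of each policy and the arbitration weight)
together with the previous trial's evidence signal for the decision's own
outcome — evidence is computed after the outcome, so the value available
when choosing is the lagged one. The weight-tertile follow-up computes
per-participant tertile boundaries with type-1 quantiles and assigns ties
to the lower tertile, making the split deterministic.

## Model-based EEG stage

`build_design()` turns a latent trace into per-event regressors. For a
feedback event showing outcome `o_i`, the correct policy assigns the
outcome to decision `i` and the incorrect policy to the other decision
`j`, so the event carries `delta_correct(d_i)`, `delta_incorrect(d_j)`,
and the outcome's own evidence signal. For response events no outcome
anchor exists, so the response-locked evidence is recombined *within* the
decision: `surprise_incorrect(d_i) − surprise_correct(d_i)`; the
cross-outcome pairing used at feedback has no natural response-time
analogue, and this within-decision contrast is the recombination the
package adopts (it remains a configurable reading rather than a settled
fact). All regressors are z-scored per participant; constant columns (for
example the weight of a fixed-weight agent) are dropped and flagged.

The mass-univariate GLM fits an ordinary least-squares regression at every
channel × time point. Betas are standardized by their per-point standard
error by default, which both equates scales across participants and
penalizes multicollinearity; residual-SD scaling and raw betas are
switches. The cluster stage thresholds one-sample t-maps at an uncorrected
two-tailed 0.05, groups supra-threshold points into signed clusters under
an explicit channel-adjacency list (a 16-channel 10-20 montage with
grid-distance adjacency ships as the default) plus consecutive-sample time
adjacency, scores clusters by mass (sum of t), and builds the family-wise
null from the maximal absolute cluster mass over random participant
sign-flips (10^4 by default; exact enumeration when fewer unique flips
exist than requested permutations). Permutation p-values use the add-one
convention, so they are never exactly zero. Analysis windows default to
0–1000 ms for feedback-locked and −500–0 ms for response-locked designs.
Downsampling to 125 Hz decimates after a zero-phase order-30 FIR anti-alias
filter normalized to unit DC gain.

The synthetic-epochs generator plants effects as separable
channel-profile × raised-cosine-window maps scaled by the z-scored
regressor, on top of first-order autocorrelated, spatially smoothed
Gaussian noise — white noise would overstate permutation power, so the
noise is deliberately structured. Ground-truth effects ride along in an
attribute for recovery tests.

## Problem sizes used by the test suite

The packaged checks run the Monte-Carlo study at its stated scale (1000
runs of 3 × 100 trials; 10,000 blocks for the walk statistic), parameter
recovery at 100 synthetic subjects, model recovery at 30 subjects per
generating model with 3 optimizer restarts, and the permutation-test
calibration at 200 null replicates on a reduced 16-channel × 64-sample
grid with 12 subjects and 250 permutations per replicate — sizes chosen so
the full suite completes comfortably on a single CPU while keeping
Monte-Carlo error well below the tolerances being asserted.

## Known limitations

- The transfer task is consumed only as per-participant accuracy; there is
  no generative model of transfer choices.
- No EEG preprocessing: inputs are assumed to be clean epochs.
- Fitting is per participant (MAP); there is no hierarchical empirical-
  Bayes pooling across participants.
- The perseveration parameter is weakly identified at 300 trials.
- The walk boundary scheme is inferred from the stability statistic, not
  from a published implementation; alternatives are kept as options.
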