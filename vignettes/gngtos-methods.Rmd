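---
title: "Models and methods behind gngtos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gngtos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices inside
`gngtos`: what the task simulator emulates, the exact model equations,
how the hierarchical sampler works, and where design decisions were
genuinely open.

## The task simulator

`make_schedule()` lays out one session of the orthogonalized
approach–withdrawal Go/No-Go task: 8 trial types (press/lift × go/no-go ×
win/avoid), 30 repetitions each, 240 trials in 6 blocks of 40 that
strictly alternate safe and threat-of-shock. Within every block each
trial type occurs equally often (5 times under the default design), so
each type contributes exactly 15 trials to each threat level. The
published description of the paradigm does not state this split; we chose
the balanced layout because it is the only one that makes the four
per-condition model fits comparable in trial count, and the schedule
validator enforces it (`trials_per_block` must be a multiple of 8,
`n_blocks` even).

Each threat block carries exactly one shock, placed at the 12th or 28th
trial with equal probability — shocks are performance-independent and are
recorded in the trial table but play no role in the learning model.
Stimulus identity (8 shapes) is welded to trial type by a per-subject
seeded permutation: a reproducible stand-in for the counterbalancing a
live experiment would use. Block order (safe-first vs threat-first)
alternates across subjects for the same reason.

`deliver_outcome()` implements the 80/20 probabilistic feedback: with
probability 0.8 the expected outcome of the emitted choice is delivered
(win trials +1 if correct else 0; avoid trials 0 if correct else −1),
otherwise the opposite member of that valence's outcome pair.

### The synthetic cohort

`simulate_cohort()` gives every subject four independent model agents —
one per TOS × Action condition, each with its own parameters drawn from
group-level normals on the sampling scale and its own latent state over
the condition's four stimuli. This mirrors the fitting assumption
(conditions are fit separately) exactly; it deliberately does *not* model
transfer of learning between safe and threat blocks for the same
stimulus, which real subjects presumably exhibit. Passing tests therefore
demonstrate that the pipeline is correct under its own assumptions, not
that those assumptions hold in human data.

Default generating values (natural scale) are literature-typical for
healthy adults on this model family: lapse `xi ≈ 0.1`, learning rate
`ep ≈ 0.2`, go bias `b = 0.3`, Pavlovian bias `pi = 0.5`, sensitivities
`rhoRew = rhoPun ≈ 4`, with spread 0.4 on the sampling scale, and **no
true condition differences** — the null configuration matches the
predominantly null condition effects this paradigm yields in healthy
samples and makes the default cohort suitable for calibration checks.

Reaction times are not part of the learning model. They are generated,
for go responses only, from a lognormal with `meanlog = log(600)` ms and
`sdlog = 0.25`, scaled by 0.97 per block — enough structure to exercise
the RT pipeline and reproduce a qualitative block speed-up, nothing more.
A withheld response has no latency; files encode it as an empty field.

## The model family

All four models share the squashed-softmax choice rule and the
sensitivity-scaled delta rule given in the README. Three decisions
deserve a note:

* **σ(0) in m4.** A zero outcome carries no information about which
  sensitivity should scale it. We scale `r = 0` with `rhoRew` (a pure
  `r ≥ 0` vs `r < 0` split), the convention of the reference
  implementations of this family; since the scaled target is `σ(r)·r = 0`
  either way, the choice only matters for code clarity, not likelihoods.
* **Lift ≡ press.** The lift condition is modeled identically to press
  with "go" meaning "lift"; the pre-trial hold prompt is not modeled.
  The fitted data are binary go/no-go choices in all four conditions.
* **Ties.** At `w_go = w_nogo` the choice rule is continuous and gives
  `P(go) = 1/2` exactly; no tie-breaking is needed.

## Hierarchical estimation

For each condition and model, subject-level parameters live on a
sampling scale where every group distribution is normal:
unit-interval parameters (`xi`, `ep`) map through the standard-normal
CDF, sensitivities through `exp`, biases are untransformed. Priors are
`Normal(0, 1)` on group means and half-`Normal(0.2)` on group spreads —
the conventions of the toolbox ecosystem around this model family, not a
claim about any particular published fit.

The sampler is an adaptive Metropolis-within-Gibbs scheme written in C++:

1. **Group means**: conjugate Gibbs draws.
2. **Group spreads**: an independence proposal from the inverse-gamma
   conditional implied by the subject deviations, which cancels the
   likelihood term exactly so the Metropolis correction reduces to the
   half-normal prior ratio.
3. **Subject parameters**: one-at-a-time random-walk Metropolis with
   per-parameter step sizes adapted toward 44% acceptance during warmup
   (Robbins–Monro, gain `0.5 / t^0.6`).
4. **Interweaving moves**: with the standardized subject effects held
   fixed, the spread (rescaling all deviations) and the mean (translating
   all subjects) are each proposed jointly with the subject values. These
   ancillary moves break the funnel coupling between group scale and
   subject effects that otherwise dominates the autocorrelation time;
   without them split-Rhat for the spread parameters stalls around 1.4–1.6
   at any affordable chain length.

Defaults are sized for desk scale: 4 chains × 500 retained draws with
1000 warmup iterations and thinning 2, which brings every group-level
split-Rhat below 1.1 on default-design cohorts in ~15–20 s. Initial
subject values are drawn near the prior mode with up to 20 retries if a
likelihood is non-finite, then the fit fails loudly. Fits exceeding
Rhat 1.1 on any quantity are flagged with a warning, never silently
accepted.

## Model comparison and inference

`compute_loo()` implements Pareto-smoothed importance-sampling
leave-one-out: raw ratios `1/p(y_i|θ_s)`, a generalized-Pareto fit
(Zhang–Stephens profile posterior, shape regularized toward 0.5 with
weight 10) to the top `min(0.2 S, 3 √S)` ratios, tail replacement by
expected order statistics truncated at the raw maximum, and
`LOOIC = −2 · elpd_loo`. Observations with shape estimates above 0.7 are
flagged. Degenerate posteriors (constant pointwise log-likelihood)
short-circuit to `−2 Σ log p(y_i)` exactly. `select_model()` sums LOOIC
over the four conditions; an exact tie is reported with the tie flag set
and the lower model index named winner.

`hdi()` is the sorted-draw shortest-interval estimator: among all windows
of `floor(mass·n)` consecutive order statistics, the narrowest. A
difference is *credible* when its interval excludes zero. Because
condition fits are independent, difference draws are paired by index
after a seeded shuffle of each vector — pairing is arbitrary under
independence, and shuffling removes within-chain autocorrelation from the
pairing. Differences are formed on the sampling scale, where the group
normal lives; the natural-scale contrast is reported alongside for
interpretation. The interaction score is the double difference
((threat press − safe press) − (threat lift − safe lift)), with the four
pairwise simple effects computed the same way.

`posterior_predictive()` re-simulates each subject on their own observed
stimulus sequence from draws of their own posterior, and reports observed
per-type accuracy against the predictive interval.

## Behavioral statistics

`rm_anova()` computes the classical univariate decomposition for fully
crossed within-subject designs from orthonormal Helmert contrasts: for
effect `E` with contrast matrix `M`, `SS_E = n‖mean(YM)‖²` and the error
term is the subject-by-effect interaction. This reproduces `aov()`'s
error-strata F tests to numerical precision (tested against both `aov`
and a brute-force linear-model oracle) while also yielding, per effect,
the Greenhouse–Geisser epsilon from the contrast covariance spectrum and
the Mauchly sphericity statistic. Sphericity is only meaningful for
effects with ≥ 3 levels (epsilon is exactly 1 at two levels); the
GG-corrected p is adopted when the Mauchly test rejects at 0.05 — the
published analyses of this paradigm do not state their trigger, so we
operationalized "violated" at the conventional level and report both
p values regardless. Partial eta squared is `SS_E/(SS_E + SS_err)`.
Subjects with any missing cell are removed listwise with a message; empty
cells are `NA`, never zero.

Paired contrasts use `df = n − 1`, the defined degrees of freedom of a
paired t test; no pooling across conditions is performed. Cohen's dz is
the mean difference over the SD of differences. When all differences are
identical the statistic is degenerate: a zero mean difference is reported
as `t = 0` (a true null effect), a nonzero one is flagged as having zero
variance rather than given an infinite t. FDR correction
(Benjamini–Hochberg via `p.adjust`) is applied within the family of
post-hoc tests for one interaction, not across the whole analysis.
RT cell means use go-response trials only, since no latency exists for a
withheld response.

`power_paired_t()` searches the smallest `n` whose exact noncentral-t
power (noncentrality `dz√n`, `df = n − 1`) reaches the target; at
`dz = 0.4`, `alpha = 0.05`, power 0.80 two-tailed this returns `n = 52`.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the stochastic
checks informative yet quick on a laptop: the parameter-recovery run uses
50 subjects × 120 trials per condition (Spearman true-vs-estimated for
`ep` and `rhoRew`); Bayesian coverage of group-mean HDIs uses 10
replicates of 15 subjects × 80 trials with generating hyperparameters
drawn from the fitting priors (so nominal coverage is exact by
construction); model recovery contrasts m1 vs m4 on 5 replicates of
20-subject default sessions; ANOVA calibration uses 500 null cohorts of
12 subjects. MCMC-based checks run 2 chains at reduced draws.

## Known limitations

* Condition-independent agents ignore cross-condition transfer and any
  within-session drift other than learning itself.
* The sampler is tuned for this likelihood family; very small cohorts
  (≲ 4 subjects) leave group spreads prior-dominated and slow-mixing.
* RT generation is phenomenological; no claim of mechanistic latency
  modeling (no drift-diffusion variant is included).
* The manipulation-check module analyzes ratings supplied by the user;
  the simulator does not generate synthetic anxiety ratings.
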