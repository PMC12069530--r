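---
title: "Population decoding and geometry for the object-in-place reward task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population decoding and geometry for the object-in-place reward task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oiprdecode)
```

## The task and the analysis problem

In the object-in-place reward (OIPR) task a subject faces five visual
scenes, each containing two objects; one object is correct and, when
chosen, yields a scene-specific reward size (small, medium or large,
nominally 0.15/0.3/0.6 ml). The five scenes are presented in a fixed order
for six consecutive runs; 5 scenes x 6 runs = one 30-trial block, after
which five entirely new scenes appear. Reward sizes are bound to scenes
under a balancing constraint: all three sizes appear among the five scenes
and no size appears three times, so each block's composition is 2+2+1 in
some order.

The analyses in this package ask two linked questions about a population of
simultaneously or serially recorded neurons:

1. **Is reward size represented, and how does the representation differ
   between task epochs?** At feedback the visual outcome explicitly signals
   the size, so a three-way representation is expected; during the delay
   (scene on screen, before the go signal) any reward information must have
   been *learned* and is predicted to follow behavior: medium and large
   reward lead to similar (exploitative) behavior while small reward
   promotes switching, so a merged medium/large representation is
   predicted.
2. **Is the upcoming stay-or-switch decision represented independently of
   reward size?** Because small-reward scenes are switched more often, the
   two labels are behaviorally correlated and must be decorrelated before
   either can be credited with neural coding.

## Pipeline overview

- `core_data`: trial-table and spike-train containers, CSV I/O, and
  event-aligned binning (`bin_spike_counts()`), default 250 ms bins moved
  in 25 ms steps. Bins are half-open `[lo, hi)`; a spike exactly on a
  boundary belongs to the later bin. The default analysis span is -500 to
  +1300 ms around the alignment event: 1800 ms gives exactly 63 bins,
  consistent with a pooled null of 20 x 63 = 1260 values, and covers a
  pre-event baseline plus the full shortest delay. The epochs' true
  analysis windows are not uniquely determined by the 63-bin count alone
  (it could also describe a concatenation of epochs); we treat it as
  per-epoch and make the span configurable.
- `synthetic_data`: a generator producing task designs, agent behavior and
  Poisson spike trains with the statistical structure the analyses assume.
- `behavior_stats`: learning curves with one-sided exact binomial tests
  against chance 0.5, pairwise chi-square comparisons of proportions,
  switch proportions with outcome conditioning, two-sample
  Kolmogorov-Smirnov tests on reaction times, and per-day aggregation.
- `pseudopopulation`: label-balanced per-neuron trial resampling,
  condition-stratified folds, and leakage-free z-scoring.
- `decoding`: time-resolved linear-SVM decoding with shuffle-null
  significance, sliding trial-window decoding within blocks, and
  balanced-sampling decoding of two correlated binary variables.
- `geometry`: projections onto the small-large discriminant and the
  overlap-index criterion.
- `encoding_models`: per-neuron variance partitioning (motor vs reward
  regressors) and the feedback visual-property ANOVA control.
- `run_pipeline()`: one-call orchestration from a YAML config with a
  reproducibility manifest; `inst/cli/oipr.R` wraps it for shell use.

## The synthetic generator defines the test conditions

The generator is not a fixture factory: its defaults *are* the conditions
every downstream claim is tested under.

**Behavior.** The agent is phenomenological, not a reinforcement-learning
model: run-1 choices are uninformed (Bernoulli 0.5 on the correct object),
and from run 2 the agent repeats its previous choice for the same scene
with a stay probability conditioned on reward size and previous-choice
correctness. Defaults: stay after a correct choice 0.70 (small) vs 0.95
(medium/large); stay after an incorrect choice 0.20 (small) vs 0.15
(medium/large). These four numbers are the minimal mechanism reproducing
the task's behavioral signature — near-perfect exploitation for
medium/large from run 2, a slower small-reward learning curve that
plateaus near 0.73, and a switch proportion that is highest for small
reward in *every* run, including run 2 where corrective switching after
run-1 errors is common in all conditions. (Small reward must switch more
both after correct *and* — slightly — after incorrect choices for the
all-trials proportion to stay on top in run 2.) Reaction times are
log-normal with a longer location for small reward (450 vs 380 ms).

**Spiking.** Inhomogeneous Poisson with a 10 Hz baseline and additive,
window-locked population gains, each scaled per neuron by a private factor
drawn uniformly in [0.5, 1.5]:

| signal | window | gains (Hz) |
|---|---|---|
| feedback reward | feedback onset to +400 ms | 0 / 5 / 10 (three levels) |
| delay reward | scene +400 ms to go signal | 0 / 6 / 6 (merged medium/large) |
| action (stay/switch) | scene +800 to +1000 ms | 0 / 5 |

The delay gain applies only from trial 15 of each block (the "learning
gate"), a trial-index threshold deliberately decoupled from the agent's
actual learning so the late-block onset of delay coding is a controllable
ground truth for the sliding-window analysis. With all gains zero the
generator is condition-blind, which is how chance levels and
false-positive rates are validated.

What the generator does *not* emulate: trial-to-trial gain correlations
(noise correlations are destroyed by pseudo-population assembly anyway),
eye movements, individual differences between subjects, and any coupling
between behavioral learning speed and neural coding strength. Passing
tests therefore demonstrate that the *pipeline* recovers designed
structure, not that real frontopolar data contains it.

## Decoding methodology

Pseudo-populations sample, per neuron and condition, a fixed number of
trials without replacement (60 per reward condition, 25 per action
condition in the reference analyses), independently across neurons; one
sample is drawn per resample and shared across time bins. Across resamples
the pool is re-sampled afresh. Folds are stratified by condition so every
fold carries equal label counts and the chance level is unbiased. Firing
is z-scored per neuron with training-fold statistics only; a neuron with
zero training variance maps to 0 rather than being dropped, keeping the
population size constant across folds.

The classifier is a linear SVM (C = 1, via libsvm/e1071). The multi-class
scheme defaults to one-vs-rest (argmax of binary decision values), with
libsvm's native one-vs-one available; the two agree closely on this data
and one-vs-one is noticeably faster, so the scaled-down acceptance runs
use it. The default k for cross-validation is 10 (compatible with 60
trials per condition and using every trial as a test trial once); k is
configurable everywhere and the scaled-down runs use k = 3-5.

**Significance.** The null model repeats the whole decoding with labels
permuted (20 shuffles in the reference design), keeping each shuffle's
across-resample mean per bin, and pools all shuffles x bins into one
distribution (1260 values at 63 bins); the Bonferroni-corrected threshold
is alpha = 0.05 / (bins x shuffles) ~ 3.96e-5. Each observed accuracy is
z-scored against the pooled null. Two p-value definitions are provided:
the Gaussian tail of that z-score (default) and the +1-corrected empirical
exceedance proportion. The empirical definition can never reach the
corrected alpha — its floor is 1/(1261) ~ 7.9e-4 with a 1260-value null —
so it cannot be the definition under which any bin is ever flagged; the
Gaussian tail of the z-score is the only reading consistent with both the
z-scoring step and a 3.96e-5 threshold, and is therefore the default.
Finally, only runs of at least five consecutive significant bins are
reported (`assess_significance()`), which also makes the procedure robust
to the noisy null-SD estimates of small shuffle counts.

**Sliding-window decoding** trains and tests within a moving window of 10
trials per block (pooled across blocks; 21 windows over a 30-trial block
in steps of 1), with a per-window shuffle null and the same
consecutive-bin rule, giving a windows x bins significance heatmap.
Eligibility requires 20 trials per condition within every window.

**Balanced decoding** decodes two binary variables (reward grouped small
vs medium+large; action stay vs switch) in one bin — the reference bin is
800-1000 ms after scene onset, where action decoding peaks — after
constructing training and test sets with equal counts in all four (A x B)
cells (70/30 split, ten repetitions, neurons with at least 10 trials per
cell). Balancing removes the behavioral correlation between the labels;
chance is exactly 50% for both variables and significance uses 25 label
shuffles, p = (1 + #{shuffled >= observed})/26.

## Geometry: discriminant projections and the overlap index

For each bin, fold and resample, both matrices are z-scored per neuron
with the mean and SD of the *small and large training trials only*; the
coding direction is mean(large) - mean(small) of training activity, and
each condition's held-out mean is projected onto it by dot product
(leave-one-trial-per-condition-out by default — the natural reading of
testing on "the remaining test trial" — configurable to coarser folds).
One hundred resamples yield a distribution of projections per condition
and bin. Pairs of distributions are compared by the overlap index: the
integral of the pointwise minimum of their Gaussian-kernel density
estimates (Silverman bandwidth, shared 512-point grid); overlap below 5%
in at least five consecutive bins marks a significant difference. The
estimator carries a small positive smoothing bias (order bandwidth²),
visible when comparing with the closed-form Gaussian overlap 2Φ(-1).
Degenerate zero-variance samples follow a point-mass rule (overlap 1 when
identical, else 0). The medium condition's position at feedback is
reported descriptively (interval containment between small and large); no
"equidistance" statistic is defined.

One property of resample-based projection distributions deserves emphasis:
their spread reflects *resampling* noise, not dataset-level sampling
noise. When the trial pool barely exceeds the number of trials sampled,
finite-pool offsets between two genuinely identical conditions can exceed
the resample spread and fake a separation. The acceptance runs therefore
keep the pool at least twice the per-condition sample, and users applying
the analysis to marginal pools should treat small overlaps with caution.

## Encoding models

Per neuron and epoch, an OLS model rate ~ RT_mov + size + RT_mov:size,
where RT_mov is the reaction-movement time (go signal to peripheral-target
touch), is summarized by sequential (Type I) sums of squares as percent of
total variance, with RT entered first — conservative for the claim that
reward size, not motor vigor, dominates; Type II is available via
`car::Anova`. Rank-deficient fits are flagged rather than silently
dropped. The epoch windows reuse the decoding windows (delay 400-800 ms
after scene onset, feedback 0-400 ms after feedback onset) since the
per-neuron models' windows are otherwise unspecified. The feedback
visual-property control runs a one-way ANOVA per neuron on rates in the
0-400 ms feedback window against shape/color labels, separately for
correct and incorrect trials; on property-blind data the selective
fraction sits at the nominal 5% false-positive rate.

## Numerical choices and degenerate inputs

- Half-open binning intervals, boundary spikes to the later bin; integer
  milliseconds on one session clock per session.
- sigma = 0 neurons map to 0 after z-scoring (never NaN, population size
  preserved).
- Chi-square without Yates correction by default (available via flag);
  zero-expected cells are flagged and the statistic computed over the
  non-degenerate cells.
- Exact one-sided binomial tests (no normal approximation); KS p-values
  asymptotic by default with an exact option for small samples.
- Incomplete blocks are excluded from block-level analyses
  (`filter_complete_blocks()`) but their trials participate in epoch-level
  decoding when counts permit.
- Every stochastic routine takes a seed and restores the caller's RNG
  state (`withr::with_seed`); fixed seeds give byte-identical outputs.

## Problem sizes used by the test-suite

The reference design (160 neurons, 60 trials/condition, 50 resamples, 20
shuffles, 63 bins, 100 projection resamples) is what the defaults encode.
The package's own validation runs use deliberately scaled-down versions of
the same procedures, chosen to exercise every rule (including the
five-consecutive-bins criterion) at small cost:

- chance recovery: 40-80 neurons, 10 blocks, 3-5 resamples, 5-25 shuffles;
- geometry recovery: 80 neurons, 24 blocks, 60 trials/condition, 100
  resamples, 250 ms bins at a 100 ms step (7-8 bins per epoch), learning
  gate opened at trial 1 so the delay geometry holds across whole blocks;
- learning-gate recovery: 80 neurons, 12 blocks, 20 resamples, k = 3,
  2 shuffles per window, 21 windows, 250 ms bins at a 100 ms step;
- balanced decoding: 80 neurons, 400 trials, 25 shuffles;
- false-positive rates: 160 neurons, 90-100 trials.

At these sizes the consecutive-bin rule requires the coded interval to
span at least five bins, which is why the scaled runs use a 100 ms step
rather than the reference 25 ms.

## Known limitations

- Pseudo-populations destroy noise correlations by construction; nothing
  here estimates their effect on decodable information.
- The shuffle null pools across bins (per the 1260-value design), assuming
  exchangeability of null accuracies across bins; per-bin nulls are
  available but need more shuffles for stable tails.
- The overlap index inherits kernel-density bias and the resampling-spread
  caveat above.
- The generator's learning gate is a step function; real delay coding
  presumably grows gradually with learning, and no within-block scaling of
  coding strength is modeled.

## A minimal end-to-end run

```{r, eval = FALSE}
library(oiprdecode)
res <- run_pipeline(default_pipeline_config(), out_dir = "oipr_demo")
list.files(res$out_dir)
```

Stage-by-stage use is shown in the README's worked example.
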