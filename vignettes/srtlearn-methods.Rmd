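---
title: "Decomposing online and offline learning in serial reaction time tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing online and offline learning in serial reaction time tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtlearn)
library(dplyr)
```

## The task and the question

In a serial reaction time (SRT) experiment, a spatial stimulus appears in one
of four locations and the participant presses the matching key; the next
stimulus follows after a fixed response-stimulus interval. When stimuli follow
a structured order, reaction times (RTs) shorten as the sequence is learned,
even without awareness of the structure. srtlearn implements the standard
analysis of such experiments for two sequence regimes:

* a **fixed sequence** — a deterministic 12-item order repeated 10 times per
  120-trial block, and
* a **probabilistic sequence** — stimuli drawn from a first-order Markov
  transition matrix in which every stimulus has one likely (0.6), one
  moderate (0.3) and one rare (0.1) successor, with no immediate repeats and
  each stimulus appearing exactly 30 times per block.

A session has six blocks: four learning blocks, a fifth block of random
stimuli that probes sequence-specific knowledge, and a sixth block that
returns to the trained sequence. The analytical question the package serves
is *how* learning accrues: **online**, within a practice block, versus
**offline**, across the rest breaks between blocks.

## Sequence generation

Fixed sequences are built as random Eulerian circuits of the complete
digraph on the four stimuli: twelve items in which every ordered stimulus
pair occurs exactly once. This satisfies the design constraints (three
occurrences per stimulus, no adjacent or wrap-around repeats, so repetitions
concatenate legally) and has a property the recall scoring relies on: each
stimulus has three *distinct* successors and each two-element context has a
unique continuation, which is exactly the structure behind the analytic
recall chance level below. A user-supplied sequence is accepted and checked.

Probabilistic blocks are sampled sequentially from the transition matrix
with the current row restricted to stimuli whose per-block quota (30) is not
exhausted and renormalized; a dead end restarts the block, with a budget of
1000 restarts. This yields exact per-block balance while pooled transition
frequencies converge to the matrix (verified by chi-square goodness-of-fit
in the test suite). The random block 5 is the special case of a uniform
off-diagonal matrix.

## The learning decomposition

After trimming (below), per participant and block:

* **Block means** and the overall contrasts `B1 − B4` (learning) and
  `B5 − B4` (random-block interference).
* **Online learning**: the slope of an OLS regression of RT on trial index
  within a block, converted to the fitted RT change over the whole block and
  sign-flipped so improvement is positive, `−slope × (n − 1)`. The
  regression summary and the break-difference below are thereby both in ms
  and directly comparable; this conversion is an interpretation choice the
  package makes explicit.
* **Offline learning**: mean RT of the last 12 valid trials of a block minus
  the mean of the first 12 valid trials of the next (one repetition of the
  fixed sequence on each side of the break).
* **Corrected offline learning**: when the previous block *deteriorated*
  (negative online learning), that deterioration is subtracted from the
  offline value, so the corrected quantity measures improvement over the
  pre-break *best* level. Under pure reactive inhibition or fatigue,
  post-rest performance only returns to that level and corrected offline
  learning is zero; genuinely offline learning makes it positive.
* **Aggregates**: online is averaged over blocks 1–4 and offline over the
  breaks 1→2, 2→3 and 3→4. Blocks and breaks touching the random block are
  reported per block/break but excluded from aggregates by default, because
  the learning claims concern the learning blocks; both switches are
  configurable arguments of `learning_summary()`.
* **Probability stratification**: for probabilistic groups the same metrics
  restricted to trials with transition probabilities 0.3 and 0.6 (the
  learnable transitions). Within-block indices are re-expressed as ranks
  among the retained trials and windows are taken over retained trials, so
  window sizes stay constant across groups; block-initial trials have no
  predecessor, carry an undefined probability and are always excluded here.

Trimming follows the standard 2.5-SD rule: within each participant-by-block
cell, mean and SD are computed once over all RTs and values strictly outside
mean ± 2.5 SD are marked invalid. Bounds are inclusive (a value exactly at
the bound is kept) because the rule removes values *greater or less than*
2.5 SD; the pass is single and never iterated, which `trim_rts()` enforces
by refusing tables that already carry a `valid` column. The rule is applied
uniformly to all six blocks, including the random block. An accuracy filter
(dropping incorrect responses before trimming) exists but is off by default.

## The synthetic cohort

Because trial-level human data for this design are not redistributable, the
package ships a phenomenological generator with known ground truth. Per
trial,

```
RT = baseline − general_practice × (block − 1) − K(block, trial)
     + prob_offset(p) + ex-Gaussian noise,
```

floored at 150 ms. `K` is the sequence-knowledge term: within a sequence
block it changes linearly so the trend RT change over the block equals
`online_rate` (negative = improvement, positive = fatigue-like slowing); at
a break between two sequence blocks it jumps so that the difference between
the last-12 and first-12 window means equals `offline_gain` *exactly*. The
jump is calibrated this way — rather than applied naively to the block-end
level — because the window means sit 5.5 trials inside each block edge;
without the calibration a nonzero within-block trend would bias the window
estimator by `−11/119 × online_rate` and the generator's parameters would
not be recoverable quantities. `offline_gain` is thus defined operationally
as what the standard offline metric measures. On the random block `K` is
withheld but not destroyed; block 6 resumes from block 4's level plus one
gain (the break following the random block contributes none).

Noise is ex-Gaussian (Gaussian σ = 45 ms plus a centred exponential tail
τ = 65 ms), the standard right-skewed model for RT data; attentional-lapse
outliers replace 2% of trials with `baseline + 1500` ms. The default cohort
preset mirrors a 2 × 2 design (preliminary knowledge × sequence type, 12
participants per cell): fixed-sequence groups improve within blocks
(online −25/−18 ms per block, with/without preliminary knowledge) with small
break gains (6 ms); probabilistic groups slow within blocks (+12 ms) and
gain substantially across breaks (30 ms); probability offsets of +22/+12/−12
ms for the 0.1/0.3/0.6 transitions order stratified RTs as 0.6 < 0.3 < 0.1.
Declarative knowledge is highest for the fixed-sequence group with
preliminary knowledge (0.6) and near zero for the probabilistic groups.
These values were fixed once as plausible magnitudes for young adults in a
millisecond-scale key-press task; they are deliberately round and are not
fitted to any data set.

What the generator does *not* emulate: error responses and post-error
slowing, autocorrelated attention drifts, chunk-boundary RT structure within
the fixed sequence, and learning-rate changes across blocks (the
within-block trend is linear by construction). Passing recovery tests
therefore show that the *pipeline* measures what it claims on data of the
assumed form, not that real RT series satisfy that form.

```{r noiseless}
d <- srt_design("fixed", seed = 7)
sim <- sim_config(
  online_rate = 20, offline_gain = 30, general_practice_rate = 0,
  noise_sigma = 1e-12, noise_tau = 0, outlier_rate = 0
)
tt <- simulate_participant(d, sim, "p1", seed = 1)
learning_summary(tt) |> select(online, offline, corrected_offline)
```

With fatigue-like slowing of 20 ms per block and 30 ms break gains, the
noiseless pipeline returns online −20, offline 30 and corrected offline 10
exactly — the closed-form accounting the test suite asserts.

## Posttest scoring and chance levels

Declarative knowledge is probed by free recall of the 12-item sequence and
by recognition of eight presented chunks (four three-element and four
four-element, half correct). Recall is scored as the number of *distinct*
three-element windows of the recalled material that belong to the design's
chunk set — the 12 cyclic windows of the fixed sequence, or the 16 triples
whose two transitions both have probability at least 0.3 — normalized by 12
or 16. A linearly written 12-item recall can expose at most 10 of the 12
cyclic windows; the package keeps the stated denominator and documents this
ceiling rather than rescaling. Recognition is the number of endorsed correct
chunks over four.

The guessing chance levels follow the conditional-guessing model: for the
fixed sequence, given the first element the second is guessed correctly with
probability 0.75 (three distinct successors among four possible guesses) and
the third with 0.25 (unique continuation), giving 18.75%; for the
probabilistic sequence each subsequent element is guessed at 0.5 among the
two learnable successors, giving 25%. Equivalently these are 12/64 and 16/64
of all stimulus triples. Recognition chance is 50% regardless of item
counts. Chance correction is by *subtraction* (the corrected value may be
negative); subtraction rather than rescaling keeps the corrected score on
the ms-free scale on which the one-sample tests against zero/chance operate.
The simulated posttest fills non-recalled slots with triples drawn uniformly
*without replacement* from all 64, so a zero-knowledge simulated participant
sits exactly at the analytic chance level in expectation — drawing with
replacement and counting distinct windows would undershoot it.

## Inference

Group-level analyses mirror SAS MIXED-style practice:

* `rm_anova()` fits the crossed fixed-effects model by generalized least
  squares under candidate residual covariance structures — compound
  symmetry, AR(1) and unstructured — and selects by AIC (REML; identical
  fixed effects make the comparison valid). F tests are marginal (type III)
  with denominator degrees of freedom by the between-within method. The
  unstructured candidate may legitimately fail on small samples; it is then
  dropped with a message and the best converged structure is used.
* `two_way_anova()` gives type-III factorial F tests (sum-to-zero
  contrasts) for the 2 × 2 knowledge-by-sequence comparisons of the
  learning measures.
* `scheirer_ray_hare()` implements the rank analogue of two-way ANOVA used
  for the recognition scores, with mid-ranks for ties, a tie-corrected total
  mean square, and chi-square reference distributions. It is invariant to
  monotone transforms of the response by construction.
* `tukey_kramer()` provides studentized-range post hocs with the Kramer
  unequal-n correction; with equal n it reduces to the ordinary Tukey HSD.
* `test_against_chance()` runs one-sample t or Wilcoxon tests of each
  group's posttest scores against that group's chance level, with the
  Bonferroni-adjusted threshold α/k (0.05/4 = 0.0125 for the four
  simultaneous group tests).

Numerical choices worth knowing: GLS optimization uses `optim` with tight
tolerances so that, on balanced two-level within data under compound
symmetry, the F statistic reproduces the squared paired t to machine-level
accuracy (asserted at 1e-6 in the tests). A constant response returns F = 0
with p = 1 rather than 0/0. Zero-variance cells in the post hoc and chance
tests are flagged and given the degenerate limits (p = 1 at the null value,
p = 0 off it).

## Calibration and recovery studies

The test suite re-derives the design constants (block structure, chunk
counts, chance levels) exactly, and runs three Monte-Carlo studies whose
sizes were fixed a priori:

* **Parameter recovery** — 50 replicate noisy cohorts of 12 participants per
  cell, all cells generated with online_rate +15 ms and offline_gain 35 ms
  (general practice 0 so the break improvement is attributable to the gain
  alone, and probability offsets 0 so the configured parameters are the
  exact trend of every cell — see the quota caveat below); the pipeline's
  mean online and offline estimates must land within 5% of the generative
  magnitudes. Residual deviation at this size comes from the trimming
  rule's mild interaction with the skewed noise (under 1 ms either way);
  the estimators are unbiased on untrimmed data.
* **Type-I calibration** — 2000 null replicates of the 2 × 2 design for the
  Scheirer-Ray-Hare and factorial ANOVA terms (rejection rates within
  [0.035, 0.065] at α = 0.05), and 300 null replicates of the full 48 ×
  6-block design for the mixed model's three-way interaction (within
  [0.025, 0.075]); the smaller mixed-model study reflects the cost of the
  three-structure fit.
* **Signature reproduction** — ten preset cohorts must show the qualitative
  pattern the preset encodes: probabilistic groups offline-dominated with
  within-block slowing, fixed groups online-dominated, and stratified RTs
  ordered 0.6 < 0.3 ≤ 0.1.

## Limitations

Exact per-block balance has a measurable side effect: as per-stimulus
quotas run out, the sampler is increasingly forced onto transitions the
matrix makes rare, so the transition-probability mix drifts near the block
end (the mean probability-offset of the default sensitivity map rises from
about −1.4 ms over trials 2–100 to +6 ms at trial 120). Real balanced
designs share this property. It means that when RT depends on transition
probability, the realized within-block trend is not exactly the configured
`online_rate` and the last-12 window sits a millisecond or two high — which
is why the recovery study above zeroes the probability offsets, and why
stratified analyses re-rank trials rather than assuming a uniform mix.

The generator is phenomenological: it makes no claims about cognitive
mechanism (no drift-diffusion, chunking or internal-model updating), and its
random-block penalty is whatever the withheld knowledge term implies rather
than an independently specified quantity, since the latter is not separable
from sequence knowledge in this design. Whether the probabilistic blocks of
a real experiment balance transition *pairs* (beyond stimulus counts) is
unspecified in the design conventions this package follows; only stimuli
are balanced here. The between-within denominator df is one of several
defensible choices for GLS F tests; with the sample sizes of this design the
practical difference from residual-based df is negligible, but exact
agreement with other software's denominator df should not be expected for
unbalanced data.
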