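---
title: "Scoring rhythm and tempo reproductions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring rhythm and tempo reproductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapscore)
```

## The scoring model

A tapping reproduction is an ordered series of timestamps; a stimulus is a
series of normative inter-onset intervals (IOIs) for a rhythm, or a single
inter-beat interval (IBI) plus a required tap count for an isochronous
tempo item. All scoring reduces to comparing two cumulative timelines:

* the reference timeline, cumulative sums of the normative intervals, with
  the first onset at time 0;
* the response timeline, cumulative sums of the inter-tap intervals (ITIs),
  anchored at the first tap.

Anchoring at the first tap makes the absolute origin of the recording
irrelevant: participants start tapping whenever the go signal allows, and
only the internal temporal structure of the response is scored. The whole
pipeline compares cumulative sums rather than interval-by-interval
differences, so a single early error propagates into later taps unless the
participant actively re-synchronises — which is the behaviour a timing
accuracy measure should be sensitive to. An alternative would be to anchor
responses at the go-beep; the package does not implement that mode, because
tap logs with arbitrary origins carry no beep reference, and first-tap
anchoring is the construction under which the package's worked-example
arithmetic is exact.

### Structural correctness

A reproduction is structurally incorrect when its note-value pattern
differs from the reference: a note value fundamentally altered, or a tap
omitted or inserted. The decision is made in two steps:

1. **Tap count.** A rhythm with `n` IOIs expects `n + 1` taps; a tempo item
   expects its specified count (8 in the standard design). Any other count
   is incorrect without further analysis — omissions and insertions cannot
   be aligned position-by-position, and the package deliberately excludes
   partial-credit alignment (edit distance, dynamic time warping): such
   alignments blur exactly the structural inaccuracies this test is meant
   to detect.
2. **Nearest-note-value classification.** Each produced interval is
   assigned to the nearest value in the item's note-value alphabet (the
   set of distinct IOIs). If the assigned value differs from the intended
   value at that position, the note value has been altered. Classification
   operates on interval *durations*, not positions: a produced 518 ms
   interval at a position whose intended value is 260 ms is nearer to a
   520 ms alphabet entry, so it counts as a substituted note value even
   though no tap is missing.

The check runs independently on two interval streams. The **absolute
stream** compares raw millisecond ITIs with the millisecond alphabet. The
**relative stream** first divides every interval by the response's (or
reference's) total span, making the verdict invariant to a global tempo
change: a rhythm reproduced perfectly at double speed is structurally
correct in the relative stream while failing the absolute one. Positions
sharing a note value share a relative value by construction, so the
relative alphabet is simply the rescaled absolute one. A response may pass
one stream and fail the other; both verdicts are retained and reported.

**Tie rule.** A produced interval exactly midway between two alphabet
values is assigned the intended value. This is deliberately conservative —
an exactly ambiguous production should not be penalised — and configurable
(`tie = "nearest_low"` resolves midpoints downward instead). Midpoint ties
have measure zero under any continuous noise model, so the choice never
affects simulated or real cohorts in practice; it exists to make the
classifier total and auditable.

### Cohort-level outlier rejection

Structural classification cannot catch a response that maps to the right
note values but contains one grossly deviant interval (e.g. a lapse of
attention stretching one 520 ms interval to 708 ms). These are removed at
the cohort level with Tukey fences at `k = 3` times the interquartile
range — the conventional "far out" rule. For a tempo item, every ITI of
every correct-count response to that item is pooled into a single
distribution. For a rhythm item, pooling is restricted to structurally
correct responses and runs separately per intended note value (all
intended-520 ms intervals across positions and participants form one
distribution, all intended-260 ms intervals another), because note values
differ in scale and would otherwise mask each other's outliers. A response
containing one or more intervals strictly outside its group's fences is
excluded whole; values exactly on a fence are retained ("at least
`k`·IQR beyond the quartile"). One outlying interval invalidates the whole
item for that participant — no partial salvage.

Numerical choices: quartiles use linear interpolation of order statistics
(`stats::quantile` type 7), the most common convention; Tukey's hinges are
available as an option and the fences used are always exported for audit.
Fence estimation needs at least 4 pooled values (configurable); smaller
groups skip the stage with a logged warning rather than estimating fences
from noise. The fence definition is inherently cohort-based, so
single-response scoring is supported by disabling the stage
(`outlier_filter = FALSE`).

### Temporal accuracy

For responses surviving both gates, accuracy is the mean percent deviation
between the cumulative timelines:

* **absolute rhythm**: `|T_k − O_k| / o_k`, averaged over all `n`
  intervals, × 100;
* **relative rhythm**: the same on span-normalised timelines, divided by
  the relative IOI, averaged over the first `n − 1` intervals — the last
  tap defines the time scale, so its deviation is identically zero and is
  excluded from the mean;
* **tempo**: `|T_k − k·IBI| / IBI` averaged over the `n − 1` intervals of
  the isochronous response.

All metrics are deviations (lower = better); `as_synchrony()` negates them
for validity analyses where synchrony should correlate positively with
ability. Internally everything is computed in full double precision;
integer-percent and 4-decimal relative values in printed output are display
rounding only (`round()`, i.e. round-half-even — the worked example's
full-precision means of 18.996% and 3.944% round to 19% and 4% under any
standard rule).

### Aggregation and participant exclusion

Participant scores are means over *surviving* items only: an item excluded
for one participant leaves their denominator rather than contributing an
imputed value, and a participant with no surviving item in a metric gets a
missing mean rather than a fabricated one. The count of correctly
reproduced rhythms uses the absolute-stream verdict by default; which
stream defines "correct" is a genuine design choice the data cannot
settle, so it is exposed (`correct_stream = "relative"` credits
tempo-shifted but structurally faithful reproductions). Cohort screening
excludes participants whose mean tempo deviation lies more than 3 sample
standard deviations from the cohort mean, and participants with zero
correct rhythms; the z rule is applied to the tempo metric only by
default, matching the test's established exclusion practice.

## Reliability machinery

Internal consistency uses McDonald's ω rather than Cronbach's α: ω only
assumes a single common factor, not equal loadings. The package fits the
one-factor model to the item correlation matrix by minimum residual
(unweighted least squares, BFGS on the off-diagonal residual sum of
squares, tolerance 1e−6, 500 iterations cap) and reports
`ω = (Σλ)² / ((Σλ)² + Σψ)`. Because incorrect reproductions leave missing
cells in the participant × item matrix, ω is computed after item-mean
imputation; the number of imputed cells is always reported, since heavy
imputation shrinks item variances and flatters ω. Dichotomous
correct/incorrect matrices are accepted and analysed with product-moment
correlations — a documented approximation (tetrachoric correlations would
be the purist's choice; they are not implemented).

Test–retest agreement is reported as a single-measure intraclass
correlation together with Spearman's ρ, which resists the leverage of
single extreme observations in small retest samples. The ICC variant is a
design choice the method description leaves open: the package defaults to
ICC(2,1) — two-way random effects, absolute agreement — because a retest
shifted systematically should not count as reliable reproduction of the
measurement; ICC(3,1) (consistency) is available by flag.

## The synthetic-cohort simulator

The simulator generates tap logs with the statistical structure the
pipeline assumes, so every stage can be validated end to end with known
ground truth. Per response it draws:

* a global tempo scale, log-normal with σ = 0.05 — reproductions are
  commonly a few percent off the target tempo;
* additive Gaussian motor jitter per interval, SD 15 ms by default (the
  worked example's single-interval deviations of roughly 10–50 ms are
  typical of untrained tappers); a Weber-fraction option scales the SD
  proportionally to interval length, since longer intervals plausibly
  carry more variance;
* at most one structural error, drawn mutually exclusively with
  probabilities `p_omit = p_insert = 0.05`, `p_substitute = 0.10` —
  so the injected structural-error rate is exactly their sum, which makes
  parameter-recovery checks sharp. Substitutions swap the intended note
  value for another alphabet value, guaranteeing a detectable
  misclassification at low jitter;
* with `p_outlier = 0.02`, one interval multiplied by U(2.5, 4),
  emulating a lapse;
* a latent per-participant ability trait (SD 0.3 on the log scale)
  multiplying jitter and shifting error log-odds, which induces the
  across-subtest score correlations a real cohort shows.

Defaults emulate a 40-participant cohort on 12 rhythm and 12 tempo items
(tempo IBIs spanning roughly 80–140 bpm, 8 taps each; rhythm alphabets
from coarse halves to sixteenth-level values across three difficulty
levels). The generator is deterministic under its seed, with
per-participant substreams at fixed offsets so one participant can be
regenerated alone.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: anticipatory (negative) asynchrony and
phase-correction dynamics, drift within a response, tap-force–dependent
sensor latency, and the heavy-tailed, occasionally bimodal error
distributions of genuinely inattentive participants. Pipeline validation
on simulated cohorts demonstrates algorithmic correctness and parameter
recovery, not human-cohort psychometrics; empirical reliability and
validity coefficients require real participants.

## Problem sizes used in validation

The test suite validates parameter recovery at 200 simulated participants
× 12 rhythm items (binomial recovery of a 0.3 injected error rate;
monotonicity of mean deviation across jitter SDs of 5, 15, 25 ms), and the
psychometric estimators against generative oracles at n = 2000 (ω of six
parallel items with loading 0.7 against the closed form 17.64/20.70;
ICC against a generated reliability of 0.8). Property checks (tempo-scaling
invariance of the relative stream, classifier equivalence with a
brute-force nearest-value oracle) run over 1000 randomised cases under
fixed seeds. These sizes give Monte-Carlo error comfortably below the
assertion tolerances while keeping the default suite fast.

## Known limitations

* Structural classification assumes the tap count is right before
  interval-level analysis; a compensated omission-plus-insertion (count
  preserved) appears as substituted note values instead — a consistent,
  but different, label.
* Item-mean imputation before ω biases towards homogeneity when
  missingness is high; `n_imputed` should always be inspected.
* The outlier stage needs a cohort; fences from very small pools (< 4
  values) are refused rather than estimated.
* Perception scoring covers the response-level rule only; stimulus
  generation and difficulty calibration of perception batteries are out of
  scope, as are presentation software and audio rendering.
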