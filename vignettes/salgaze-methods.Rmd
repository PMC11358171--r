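---
title: "salgaze: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{salgaze: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`salgaze` analyses *what observers look at* in surveillance-style video.
Given per-frame gaze positions for two groups of observers (an
experienced, "operator-like" group and a novice-like group) watching the
same clips, it asks whether the visual content at fixation — scored
either by a low-level saliency model or by a semantic embedding —
differs systematically between groups, and how consistent each group is
internally. Because real eye-tracking corpora of this kind are rarely
shareable, the package includes a synthetic world (clips, gaze, ratings)
with controllable group structure, so every stage of the pipeline is
testable end to end.

The pipeline is: gaze-centered **patch extraction** → per-frame
**feature extraction** (saliency channels or embeddings) → per-clip
**group decoding** over cumulative temporal windows and
**inter-subject correlation** (ISC), plus **signal-detection scoring**
of behavioral ratings.

## Gaze-contingent patches

`extract_patch_sequence()` crops a `w × w` patch (default 75 px,
roughly 3° at the default geometry; 38 and 150 px are the usual
robustness alternatives) around the rounded gaze position of every
frame. Conventions, fixed so the crop is exhaustively testable:
coordinates are 0-based, `x` = column, `y` = row, origin top-left; the
crop starts at `round(c) − floor(w/2)`, so odd windows are symmetric
about the fixation and even windows map it to index `w/2`. Crops that
overhang the frame are zero-padded by default (`boundary = "clamp"` is
available); frames with missing gaze yield all-zero patches, which is
also what the downstream models consume — missingness is data here,
not something to impute. `downsample_frames()` keeps every tenth frame
(indices 0, 10, 20, …) for the embedding stream.

## The saliency model

Six channels are computed per patch (`decompose_channels()`):

* **Luminance** `L + M`, **red–green** `L − M`, **yellow–blue**
  `(L + M) − S`, where LMS cone responses come from a fixed
  Hunt–Pointer–Estevez matrix composed with the sRGB/D65 primaries.
  Inputs are treated as linear RGB in [0, 1] (no gamma model — the
  synthetic stimuli are generated in linear intensities).
* **Orientation**: max quadrature energy over a Gabor bank, 4
  orientations (0°, 45°, 90°, 135°) × 2 wavelengths (1/4 and 1/8 of the
  patch side, envelope σ = λ/2).
* **Texture**: max absolute response of a center-positive
  Laplacian-of-Gaussian bank at σ = 1/16, 1/8, 1/4 of the patch side.
  The center-positive (negated-Laplacian) polarity matters: the
  rectified center-surround cascade below must respond *at* a bright
  blob, not on the ring around it.
* **Optical-flow magnitude**: local least-squares (orientation-tensor /
  Lucas–Kanade-type) estimate over a 5 × 5 neighbourhood from the
  previous and current grayscale patch; magnitude only, zero on the
  first frame. Magnitudes are clamped at half the patch side per frame:
  where the local gradient system is near-singular (the aperture
  problem) the unregularised solution can explode to nonphysical
  speeds.

Each channel map feeds a 4-level Gaussian **pyramid** (blur σ = 1, then
ceiling-halving decimation: 75 → 38 → 19 → 10), and each level receives
five passes of **center-surround activation** (LoG convolution →
half-wave rectification → Gaussian blur). All filtering uses
edge-replicate padding so that zero-mean kernels respond with exact
zeros on constant images.

**Normalization.** Per channel, the raw factor is the sum of map values
at or above the 90th percentile ("regions that locally stand out"),
pooled over pyramid levels. The raw factor is blended with the factors
of the previous two frames as a (1, 0.5, 0.25)-weighted **mean** —
chosen so that a static input is a fixed point of the blend — and all
maps of the channel are divided by the blended factor. The six blended
factors are the frame's exported features; concatenated over a
400-frame clip they form the 2,400-element vector used for decoding and
ISC. Channels whose raw factor falls below `factor_epsilon` (1e-10) are
flagged and exported as 0 with a no-op divisor: without this floor, the
division would amplify float-level residue of constant maps into
order-one saliency. In particular, blank missing-data frames export
all-zero features.

**Fusion.** Levels are upsampled to the base scale, summed and divided
by the stack size per channel; channel maps are summed; the per-frame
maps of the previous two frames are added with weights 0.5 and 0.25 (a
(1, 0.5, 0.25)-weighted **sum**, unlike the factor blend: a transient
event's contribution then halves on each subsequent frame and vanishes
after two); a logistic `1 / (1 + exp(−k (s − s₀)))` squashes the result
to [0, 1]. The defaults `k = 154`, `s₀ = 0.0192` were calibrated once so
the empirical map distribution spans roughly [0.05, 0.95] on
default-scale synthetic fixtures, and not revisited. `saliency_index()`
is the mean of the final map over a gaze-centered region (the full
patch by default, since the model runs on gaze-centered patches — an
open design point; a full-frame mode would only change what the patch
is cropped from).

The per-frame feature the analyses consume is the exported
normalization-factor 6-vector (the quantity described as exported for
subsequent analysis), not the patch-mean channel activation.

## Semantic embeddings

`embedding_backend()` abstracts the patch-to-vector map. The default
backend is a deterministic seeded random projection: the patch is
bilinearly reduced to 8 × 8 × 3, multiplied by a fixed Gaussian matrix
(4096 rows by default, mimicking a classic FC7 layer) and half-wave
rectified (post-ReLU convention). It is linear-then-ReLU by design:
locality is bounded by the operator norm, which keeps decoding tests
stable, and a zero patch maps to the zero vector. A pretrained-CNN
backend is deliberately not bundled (it would require a weight
download); requesting it raises a capability error naming the stub.
All downstream code depends only on `output_dim`.

## Group decoding

`loo_group_decode()` fits an elastic-net-penalised binomial GLM
(`glmnet`, mixing weight α = 1 by default; 0.9/0.8 exposed) to all
participants but one and predicts the held-out participant, cycling
over all (21 iterations for 11 + 10). Features are concatenated over
**cumulative windows** anchored at clip onset (step 50 frames for the
saliency stream, 5 on the 10×-downsampled embedding grid; 8 windows
either way), and each clip is summarised by its **maximum** window
accuracy (ties keep the earliest window). Per-category one-sample
t-tests against 0.5 use a Bonferroni-adjusted alpha (0.0125 for four
categories). A channel-shuffling **permutation test**
(`permutation_null()`) relabels the six saliency channels per
participant, consistently across frames, and re-runs the whole pipeline
per iteration; `selection_proportions()` reports how often each channel
carries a nonzero coefficient.

Numerical and small-sample choices:

* **Regularisation strength**: inner stratified 5-fold CV on the
  training fold (seed-controlled), over glmnet's 30-step path. When a
  training class has fewer than 4 members no CV split can keep both
  classes in every fold, so the fit falls back to a fixed mid-path
  lambda (2/3 down the path) — deterministic, and only relevant to
  scaled-down test worlds, not the 11 + 10 design.
* **Balanced class weights** in *all* decoders, not only fight-vs-rest.
  This is load-bearing: in leave-one-out the held-out participant's
  class is always the training minority, so an intercept-dominated fit
  predicts every single participant wrong (anti-learning) instead of
  sitting at chance. With balancing, null-world accuracy is calibrated
  at 0.5 and genuine signal decodes. A related caution, asserted in the
  tests: on label-balanced null data, LOO accuracy sits at or slightly
  *below* chance, never exactly at 0.5.
* Probability threshold 0.5, ties to the alphabetically first class;
  feature standardisation happens inside glmnet on the training fold
  only.

`decode_fight_vs_rest()` runs the per-participant action decoding
frame by frame with leave-one-clip-out, takes the maximum accuracy per
4-s chunk and averages chunks; the majority-class prior (27/36 with the
default set) is reported alongside. `combine_streams()` concatenates
per-frame saliency and embedding blocks after standardising each
stream; `correlate_behavior()` produces the Pearson r / p table against
the signal-detection scores.

## Inter-subject correlation

`znorm_channels()` standardises each feature channel over the pooled
clip × participant × frame axis (population-sd convention, divide by
N). `pairwise_isc()` is the mean Pearson correlation over all
within-group pairs of time-concatenated feature rows;
`time_resolved_isc()` applies it per 2-s chunk (eight chunks of a 16-s
clip; per-chunk group comparison by a two-sample t-test on
Fisher-z-transformed pairwise correlations at alpha 0.05/8).
`intergroup_correlation()` correlates each participant with the mean
feature row of their own group (leave-self-out by default, to avoid
self-correlation inflation; both modes exposed) and of the other group.
Zero-filled missing frames are retained in the concatenated vectors, as
in the main analyses; excluding them is a caller-side filter.

## Behavioral scoring

Fight clips rated ≥ 4 are hits; non-fight clips rated ≤ 3 are correct
rejections. `dprime_criterion()` computes `d′ = Φ⁻¹(H) − Φ⁻¹(F)` and
`C = −(Φ⁻¹(H) + Φ⁻¹(F))/2` with the log-linear correction (+0.5 per
cell, +1 per denominator) for extreme rates — a standard choice; the
original study does not state its correction, which is a genuine
reproducibility caveat.

## The synthetic world

`generate_stimulus_set()` renders four action categories of moving
Gaussian-blob "agents" (fight: accelerating convergence on an
interaction locus; confrontation: approach to a stand-off;
playful: orbiting; neutral: independent slow walks) plus static or
periodically flashing high-contrast distractors, at the default format
of 36 clips (9 per category), 16 s at 25 fps, 576 × 480 px. Frames are
rendered lazily (`clip_frame()`); a materialised default clip would be
~2.6 GB. Ground-truth agent tracks are stored exactly, which is what
makes the gaze generator and the tests possible.

`generate_cohort_gaze()` (default 11 operator-like + 10 novice-like
participants) has every participant track the agent that ends nearest
the interaction locus, with a persistent participant-specific bias
(sd 50 px at the reference frame width, scaled by `1 − consistency`)
and smooth AR(1) wander. Novice-like participants are additionally
captured by a random distractor in each 0.5-s dwell segment with
probability `min(1, 0.6 × strategy_gap)`. Dispersion scales with frame
width (constant in visual-angle terms), so scaled-down worlds keep the
full-scale geometry — without this, test-scale frames lose all content
signal. Missing frames are i.i.d. Bernoulli at 1.1% (only the mean rate
is known); gaze is generated at frame rate, since all analyses are
per-frame. With `strategy_gap = 0` and equal consistencies the two
groups are draws from one generative policy — the null world used for
calibration tests.

`generate_ratings()` draws a decision variable from an equal-variance
Gaussian signal-detection model (fight clips carry the signal) and bins
it by five equal-width cuts 0.5 z-units apart centered on the
criterion, so the binary "violent" judgement cut *is* the criterion
parameter and the generating sensitivity is recoverable as d′
(round-trip tested to ±0.2 at 10,000 trials).

**What the generator does not emulate** — and hence what a green test
does not establish: photorealistic people and scenes, saccade/fixation
micro-structure (50 Hz tracker noise, blinks), object semantics beyond
blob color/motion, and the magnitudes of the original study's effects.
The acceptance tests check *structure* (counts, shapes, calibration,
monotone recovery of injected effects, qualitative operator > novice
direction), not the published accuracy or ISC values, which would
require the original footage and eye-tracking data.

## Known limitations

* The saliency channels run on the extracted patch, so patch-border
  effects (edge-replicate padding) enter the maps; classic
  saliency-model descriptions leave many filter parameters open, and
  ours are therefore declared explicitly in `saliency_config()`.
* The stub embedding is a fixed random projection: good for pipeline
  semantics and determinism, silent on real object content.
* Leave-one-out decoding at n ≈ 20 has coarse accuracy granularity
  (1/21) and residual anti-learning bias on null data; the permutation
  machinery, which shares the bias between observed and null, is the
  more trustworthy inferential tool at this scale.
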