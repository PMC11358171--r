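# salgaze

Saliency and semantic feature analysis of gaze-contingent video
content.

When two groups of observers — say, experienced surveillance operators
and novices — watch the same video clips, do they *look at different
things*? `salgaze` answers this by scoring the content at each
fixation rather than the fixation coordinates themselves: it crops a
gaze-centered patch from every frame, scores it with a six-channel
spatiotemporal saliency model (luminance, red–green and yellow–blue
cone-opponent color, Gabor orientation energy, multi-scale LoG texture,
optical-flow magnitude — with Gaussian pyramids, five-pass
center-surround activation and a two-frame temporal buffer with 0.5
decay) or with a pluggable semantic embedding backend, and then asks
two questions of the per-frame feature streams:

* **Decoding** — can an elastic-net-penalised logistic regression
  (mixing weight α = 1), trained leave-one-participant-out on features
  concatenated over cumulative temporal windows, tell the groups apart?
  Each clip is scored by its maximum window accuracy
  `max_w acc(w)`, tested per action category against chance 0.5 at a
  Bonferroni-adjusted alpha (0.05/4), with a channel-shuffling
  permutation null.
* **Inter-subject correlation (ISC)** — how similar are the
  time-concatenated feature vectors within each group? For a group of
  n observers, ISC is the mean Pearson r over all n(n−1)/2 pairs, per
  clip, also resolved into 2-s chunks and against own/other group mean
  features.

Behavioral violence-likelihood ratings (1–6) are scored with signal
detection theory: rating ≥ 4 on a fight clip is a hit, giving
`d′ = Φ⁻¹(H) − Φ⁻¹(F)` and `C = −(Φ⁻¹(H) + Φ⁻¹(F))/2` (log-linear
corrected).

Since data of this kind are rarely shareable, the package ships a
synthetic world — category-dependent moving-blob clips, a two-group
gaze generator with a controllable `strategy_gap` (how often the
novice-like group is captured by distractors) and
`within_group_consistency`, and a signal-detection rating generator —
so the full pipeline runs and is tested without any download.

## Worked example

```r
library(salgaze)

# a small world: 4 clips (one per action category), 3 + 3 observers
base   <- clip_spec(duration_s = 0.8, fps = 25, width = 48L, height = 48L,
                    n_agents = 2L, n_distractors = 1L,
                    distractor_salience = 0.8)
clips  <- generate_stimulus_set(1L, base, seed = 1)
cohort <- cohort_spec(3L, 3L, gaze_noise_px = 1, seed = 2)
traces <- generate_cohort_gaze(clips, cohort)

fm  <- cohort_feature_matrices(clips, traces, "saliency", window_px = 16L)
dec <- decode_group_membership(fm, step = 20L, seed = 3, nfolds = 3L)
isc <- cohort_isc(fm)
sdt <- dprime_criterion(score_outcomes(
         generate_ratings(cohort, clips, seed = 4)))

mean(dec$per_clip$accuracy)          # group decoding accuracy
tapply(isc$isc, isc$group, mean)     # within-group ISC
mean(sdt$d_prime)                    # behavioral sensitivity
```

Running exactly this configuration via the bundled smoke run
(`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
prints:

```
smoke run ok: 4 clips, mean decoding accuracy 0.667, ISC a/b 0.729/0.323, mean d' 1.30
```

Read: from gaze-centered saliency features alone, the leave-one-out
classifier assigns two thirds of observers to the correct group; the
operator-like group ("a") is far more internally consistent in the
saliency content it fixates (ISC 0.73 vs 0.32) because its gaze
follows a shared agent-tracking policy while the novice-like group is
intermittently captured by distractors; and the rating generator's
default sensitivities land the cohort's mean d′ at 1.30. The
acceptance script writes an empty JSON object (`{}`): the build's
acceptance checks are property-based and live in the test suite, not
in numeric report targets.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/salgaze.R", package = "salgaze"))')
Rscript $CLI synth  --n-per-category 9 --operators 11 --novices 10 --seed 1 --out data/
Rscript $CLI decode --in data/ --stream saliency --step 50 --seed 1 --out decoding.json
Rscript $CLI isc    --in data/ --stream saliency --out isc.csv
```

`synth` writes `manifest.json` (clip specs + seeds, enough to
regenerate every frame exactly), `gaze.csv`
(participant_id, group, clip_id, frame, x, y, valid; 0-based
coordinates, origin top-left) and `ratings.csv`.

See `vignettes/salgaze-methods.Rmd` for the full model description,
parameter conventions, numerical choices and limitations.
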