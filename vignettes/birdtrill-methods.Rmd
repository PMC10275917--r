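---
title: "Measuring vocal consistency and modelling playback habituation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vocal consistency and modelling playback habituation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birdtrill)
```

## The measurement problem

Many songbirds sing trilled songs: a few introductory notes followed by
a trill in which a single note type is repeated in rapid succession.
How precisely a male reproduces the same note — his *vocal
consistency* — is a motor-performance trait, and receivers can assess
it quickly because the reference (the previous rendition) is only a
fraction of a second away. birdtrill implements the full measurement
and analysis chain for this trait: scoring consistency from annotated
audio, describing its within-bout dynamics, building the playback
stimuli used to probe female preferences, and fitting the
habituation/dishabituation response models.

## Vocal consistency by spectrogram cross-correlation

Each annotated note is cut from the recording (half-open sample windows
with round-to-nearest endpoints, so any partition of a clip
concatenates back exactly), brought to one common analysis rate
(default 48 kHz) and transformed to a linear-magnitude spectrogram:
Hanning window of 512 samples, 90% overlap, magnitude (not power, not
dB) of the one-sided FFT.

The SPCC score of two notes is the maximum over temporal offsets of
the Pearson correlation between their spectrograms, computed over the
overlapping frame range with frequency × time cells flattened.
Numerical choices worth stating:

* **Lag grid.** The nominal search is ±20 ms in 1 ms steps. With a
  512-sample window at 90% overlap the hop is `round(51.2) = 51`
  samples ≈ 1.0625 ms at 48 kHz, so offsets are realized on the native
  frame grid: the 1 ms candidates are rounded to whole frames and
  deduplicated. This is the closest realizable version of the nominal
  grid; correlations at sub-frame offsets are not interpolated.
* **Overlap handling.** Notes of unequal length are compared over their
  overlapping frames at each lag; a lag leaving fewer than 3
  overlapping frames is skipped. This keeps the statistic defined for
  the short, similar-length notes of a trill without rewarding tiny
  accidental overlaps.
* **Degenerate input.** A comparison in which every candidate lag has
  zero variance (silence against silence) returns 0 with a warning
  rather than NaN; notes shorter than one FFT window are zero-padded to
  one window so they remain computable.
* **Normalization.** Pearson correlation on linear magnitude gives the
  bounded [−1, 1] contract with self-similarity exactly 1, the common
  SPCC convention; no frequency-band restriction is applied by default.

The consistency of note *i* is the mean SPCC of note *i* against every
other trill note (the off-diagonal row mean); the vocal consistency of
the song is the mean of the note scores, which by symmetry equals the
mean over unordered pairs. Consistency is undefined for trills with
fewer than two notes; such songs are kept in the data but flagged
ineligible, mirroring the screening-out of song types with very short
trills in field practice.

```{r spcc-demo}
song <- synthSong(synthSongConfig(freqJitterSd = 80), seed = 1)
res <- songConsistencyFromSong(song)
songScore(res)
```

## Song-type bouts and the warm-up effect

Males repeat one song type many times (a *song-type bout*, at least
three renditions) before switching or falling silent. `segmentBouts()`
starts a new bout at the session start, at any type change, and after a
silent pause longer than 60 s — even without a type change. The pause
is measured from the end of one song to the start of the next (the rule
could equally be onset-to-onset; end-to-onset is the natural reading of
a "silent pause" and is what we implement). When a long pause and a
type change coincide, the boundary is classified as a silence gap,
because the pause rule applies regardless of switching. Runs of fewer
than three songs are emitted flagged sub-minimal rather than dropped,
so every input song is accounted for exactly once.

Within each bout the first 15 repetitions are selected and consistency
is standardized by subtracting the first song's value (position 1 is
exactly 0). `warmupTrend()` fits the standardized series against
repetition number with a random intercept per male — a single
individual-level variance term, matching how such warm-up effects are
reported. Standardizing against the first song makes all errors within
a bout share the first song's noise; that shared term inflates the
estimated residual variance and so makes the slope CI conservative,
which we accept as the cost of the interpretable position-1-equals-zero
scale. With a single individual the grouping term is degenerate and the
function falls back to OLS with a warning.

Seasonal summaries bin songs into whole weeks relative to the male's
first-egg date by floor division, so the first-egg date falls in week
0, and centre consistency within individual (the binning rule is a
package choice; nothing downstream depends on where within a week the
boundary falls). Fitting smooth seasonal curves is out of scope — the
table is the input one would hand to a GAMM.

## Playback stimulus construction

The female-choice stimulus is built from one exemplar song per song
type, repeated verbatim at the male's measured natural song rate: song
onsets at multiples of `60/rate` seconds while the whole song fits
inside a 75 s bout, silence-padded to exactly 75 s. Two bouts (one per
type) make a 150 s song section; with a 150 s silence section they form
a 5-minute round. Twelve rounds follow a ≥ 300 s lead silence; the
song/silence order within each round and the A/B order within each
song section are independent fair seeded draws, making the schedule a
pure function of its inputs — 24 song-type bouts, 1800 s of song and
1800 s of round silence per trial, always. No balance constraint is
imposed on the randomization because none is part of the design; the
draws are simply independent per round.

Rendering peak-normalizes to −3 dBFS, the digital counterpart of
calibrating speaker level in the field, and emits a cue table with
every song onset and its position within its bout. Each song-type bout
is classified by what immediately precedes it: a silence section
(`silence_gap`) or another song-type bout (`type_switch`). A full trial
at 48 kHz is ~190 M samples; rendering at a lower rate is advisable
when the audio itself is not needed, and the schedule/cue machinery is
rate-independent.

## Response scoring and the habituation model

Only calls associated with copulation solicitation displays
(`copulation`, `twittering`, `chattering`) count as response; churring,
screaming and unclassified calls are ignored. A song position scores 1
if at least one such call falls between its onset and the next onset
(bout end for the last song); a bout's binomial response is whether any
position scored. Bouts played entirely while the female was out of the
box are removed; partial presence is retained with its in-box fraction
reported, since the field protocol only excluded bouts played to an
absent female.

The habituation model is a binomial GLMM: response ~ scaled log
position × switch indicator + (1 | female). Conventions:

* log position uses the natural log with positions starting at 1;
* the log-position predictor is centred and scaled on the observed
  rows, through the same `scaledLogPosition()` utility the simulator
  uses, so simulation-and-refit recovery is exact in expectation;
* the switch indicator is 0/1 with silence-preceded bouts as the
  reference level, so the intercept is the response at position 1 of a
  bout preceded by silence;
* estimation is Laplace-approximate ML via `lme4::glmer` (Bernoulli
  rows are aggregated to binomial counts per female × category ×
  position, which leaves the likelihood unchanged and speeds fitting);
* CIs are Wald on the logit scale, back-transformed endpoint-wise with
  the inverse logit — the same relationship that links the
  logit-transformed and back-transformed halves of a published
  coefficient table;
* complete separation is detected heuristically (non-finite or huge
  standard errors, |estimate| > 10) and flagged in the returned report;
  no penalized refit is attempted, the flag is the documentation.

The preference model follows the same conventions with bout successes/
failures per song type per trial against centred/scaled vocal
consistency, song rate and trill length. All three acoustic predictors
are exposed even though reported tables sometimes retain only a
subset — model selection decides. `preferenceModelSelection()` fits
every predictor subset, ranks by AICc, averages the ΔAICc < 2 set with
full (zero-substitution) averaging — the convention implied by "full
average model" terminology — and reports per-variable relative
importance (summed weights) plus everything below ΔAICc < 7. VIF
screening (`vif()`, flag at 3) works on the raw design matrix.
Treatment-level Song vs Silence comparisons use the paired Wilcoxon
signed-rank test, exact for ≤ 25 untied nonzero pairs.

## The synthetic-data generator

Synthetic notes are frequency-swept sinusoids with per-note jitter:
frequency `f0 + N(0, freqJitterSd)`, duration jittered and clamped at
25% of nominal, raised-cosine ramps, amplitude jitter, white noise at a
set fraction of tone RMS. Intro notes sit at a higher frequency and are
excluded from consistency (the analysis uses the trill only).
Annotations align with the rendered audio to the sample, so the
end-to-end identity holds: zero-jitter songs measure consistency 1.

Defaults emulate a small trill: 2 intro + 5 trill notes of 50 ms at
4 kHz with a shallow downsweep, 50 Hz frequency jitter, 3 ms duration
jitter, 5% amplitude jitter, 1% noise — values a field recordist would
call a clean, moderately stereotyped recording. What the generator
does *not* emulate: real blue tit timbre and harmonic structure,
reverberation, wind and dawn-chorus background, amplitude fades from
bird movement, or song-type syntax beyond intro+trill. Passing tests
therefore demonstrate that the measurement chain is correct and
sensitive to jitter dose (consistency decreases monotonically in
frequency jitter, duration jitter and noise), not that any particular
absolute score should be expected in the field.

Dawn sessions compose bouts with >60 s pauses (same-type boundaries)
or continuous type switches, returning per-song clips, sample-exact
annotations and a ground-truth bout table that segmentation must
recover exactly. The session is deliberately returned as per-song
clips rather than one assembled multi-minute waveform: segmentation
operates on timing metadata, and a 48 kHz hour-scale waveform would
only consume memory. The warm-up effect is injected by *reducing
frequency jitter across repetitions*, not by setting consistency
directly — consistency is a derived measurement, so
`calibrateWarmupJitter()` probes the jitter→consistency curve by Monte
Carlo and inverts it to hit a target slope.

Two numeric-level generators complement the audio path where audio
adds nothing: `simulateWarmup()` draws per-song consistencies from the
warm-up generating process (per-repetition increment 0.002, residual
SD 0.074, individual SD 0.028, 18 males × 4 bouts × 15 positions by
default), and `simulateResponses()` draws Bernoulli responses from the
logistic habituation process (intercept 0.052, switch −0.813,
log-position −1.039, interaction 0.532, female SD 0.87; 100 females ×
8 bouts — half silence-preceded, half switch-preceded — × 15
positions). These defaults *are* the study conditions for the recovery
analyses; they are not tuning knobs.

## Problem sizes and verification

The test suite verifies: oracle equivalence of `spccPair()` against a
brute-force lag enumeration and of the signed-rank p-values against
exhaustive sign enumeration (n ≤ 10); the pair-mean identity of song
consistency; shift invariance within ±20 ms; exact recovery of
synthetic bout structure; and parameter recovery for both mixed
models. Monte-Carlo checks use 40–60 seeded replicates per condition
and recovery suites use 50 simulation-refit replicates at the default
generator sizes, sizes at which the dose-response and coverage
properties are statistically stable while the whole suite stays
comfortably fast. Coverage assertions use the 90% threshold
appropriate for 95% Wald intervals under these designs.

## Known limitations

* SPCC is the only similarity measure; no DTW or cepstral distances.
* Note segmentation is taken from annotations — no automatic detection.
* Song types are input labels; no clustering or classification.
* Wald CIs can undercover in small, unbalanced designs; the recovery
  suites quantify this for the default designs only.
* The separation fallback is a flag, not a penalized estimator.
* Audio-level warm-up calibration is Monte-Carlo approximate; the
  numeric-level generator is the reference for quantitative recovery.
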