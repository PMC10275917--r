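# birdtrill

Tools for quantifying **vocal consistency** — the precision with which a
songbird repeats the same note — and for analysing how female receivers
respond to repeated and switched song in playback experiments. The
package targets trilled song of the kind blue tits (*Cyanistes
caeruleus*) produce: a few high-pitched introductory notes followed by a
trill in which one note type is repeated in rapid succession. It is
aimed at bioacousticians and behavioural ecologists working with
annotated field recordings or designing nest-box playback trials.

## What it computes

**Vocal consistency by spectrogram cross-correlation (SPCC).** For two
notes with magnitude spectrograms *A* and *B* (FFT window 512 samples,
90% overlap, Hanning window), their SPCC score is

    SPCC(A, B) = max over lags τ, |τ| ≤ 20 ms, of  cor( A|τ , B|τ )

the Pearson correlation of the overlapping frequency × time cells at
temporal offset τ, searched on a ~1 ms lag grid. The consistency of a
note is the mean SPCC score against every other note in the trill; the
vocal consistency of a song is the mean over its trill notes (equal, by
symmetry, to the mean over all unordered note pairs). Scores live in
[−1, 1] and sit near 1 for precisely repeated trills.

**Song-type bouts and the warm-up effect.** Continuous singing is
segmented into song-type bouts — runs of ≥ 3 renditions of one song
type, broken by a type switch or a silent pause > 1 min. Within a bout,
consistency is standardized against the first song and its rise over
the first 15 repetitions (the warm-up) is estimated with a linear mixed
model (random intercept per male).

**Playback stimuli.** One-hour dual-song-type stimuli: ≥ 5 min lead
silence, then 12 five-minute rounds, each one 150 s song section (two
75 s song-type bouts, both types) plus one 150 s silence section in
seeded random order — 24 song-type bouts per trial, rendered to audio
with a cue table of every song onset.

**Habituation / dishabituation.** Female responses (binary per song:
any copulation-solicitation-class call) are modelled with a binomial
GLMM on centred/scaled log song position, a switch-preceded indicator,
their interaction and a female random intercept. A negative
log-position coefficient is habituation; a positive interaction is
partial recovery after a song-type switch. Wilcoxon signed-rank
comparisons, AICc ranking, ΔAICc < 2 full-model averaging, relative
importance and VIF screening round out the analysis toolkit.

**Synthetic songbird data.** Every stage is testable without field
recordings: `synthSong()` renders annotated trilled songs with
controllable frequency/duration/amplitude jitter and noise,
`synthDawnSession()` builds dawn sessions with known bout structure and
a calibrated warm-up, and `simulateResponses()` draws binary female
responses from the logistic habituation process.

## Worked example

```r
library(birdtrill)

## a synthetic song: 2 intro notes + 5 trill notes, 80 Hz frequency jitter
song <- synthSong(synthSongConfig(freqJitterSd = 80), seed = 1)
song
#> AnnotatedSong s1: male m1, type A, dawn, 7 notes (5 trill)

res <- songConsistencyFromSong(song)
res
#> ConsistencyResult: 5 trill notes, vocal consistency 0.9835
round(noteScores(res), 3)
#> [1] 0.999 0.998 0.960 0.961 0.999
```

The song-level score 0.9835 is the mean pairwise SPCC over the trill;
the per-note scores show which renditions drifted (notes 3–4 took the
larger frequency jitter draws here).

```r
## dawn session with known bout structure, segmented back
ses <- synthDawnSession(
  list(A = synthSongConfig(), B = synthSongConfig(f0 = 4600)),
  boutTypes = c("A", "B", "B"), boutLengths = c(5, 4, 6), seed = 2)
segmentBouts(ses$songTable)[[2]]
#> SongTypeBout m1_b02: male m1, type B, 4 songs, preceded by type_switch

## habituation: simulate from the published process, refit
d <- simulateResponses(nFemales = 100, seed = 3)
fit <- fitHabituationModel(d)
fit$coefficients[, c("term", "estimate", "ciLower", "ciUpper", "backTransformed")]
#>                 term estimate ciLower ciUpper backTransformed
#> 1        (Intercept)   0.0743 -0.0885   0.237           0.519
#> 2        logPosition  -1.0449 -1.1163  -0.973           0.260
#> 3             switch  -0.8410 -0.9244  -0.758           0.301
#> 4 logPosition:switch   0.5020  0.4112   0.593           0.623
round(fit$femaleSD, 2)
#> [1] 0.77
```

The recovered coefficients sit on top of the generating values
(0.052, −1.039, −0.813, 0.532; female SD 0.87): response declines with
log repetition (habituation) and partially recovers after a song-type
switch (positive interaction). `backTransformed` is the inverse logit
of each estimate.

## Vignette

`vignettes/birdtrill-methods.Rmd` documents the measurement model, the
statistical models and their assumptions, the synthetic-data generator,
and the numerical design choices.
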