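#' Configuration for a synthetic trilled song
#'
#' Defaults emulate a small trilled song: a couple of higher-pitched
#' introductory notes followed by a trill of one repeated note type
#' around 4 kHz with a shallow downsweep, with note-to-note jitter in
#' frequency, duration and amplitude plus additive white noise. The
#' trill must have at least 3 notes, matching the screening-out of very
#' short trills from consistency analysis.
#'
#' @param nIntro number of introductory notes (default 2).
#' @param nTrill number of trill notes (default 5, >= 3).
#' @param noteDuration nominal note duration, seconds (default 0.05).
#' @param interNoteGap silent gap between notes, seconds (default 0.03).
#' @param f0 trill note start frequency, Hz (default 4000).
#' @param sweep linear frequency sweep, Hz/s (default -8000, a shallow
#'   downsweep).
#' @param introMultiplier intro-note frequency multiplier (default 1.6,
#'   making intro notes higher pitched than the trill).
#' @param freqJitterSd SD of per-note frequency jitter, Hz (default 50).
#' @param durationJitterSd SD of per-note duration jitter, seconds
#'   (default 0.003).
#' @param ampJitterSd SD of per-note relative amplitude jitter
#'   (default 0.05).
#' @param noiseLevel additive white-noise RMS as a fraction of the tone
#'   RMS (default 0.01).
#' @param rate sampling rate, Hz (default 48000).
#' @return list of class `synthSongConfig`.
#' @export
synthSongConfig <- function(nIntro = 2L, nTrill = 5L, noteDuration = 0.05,
                            interNoteGap = 0.03, f0 = 4000, sweep = -8000,
                            introMultiplier = 1.6, freqJitterSd = 50,
                            durationJitterSd = 0.003, ampJitterSd = 0.05,
                            noiseLevel = 0.01, rate = 48000) {
  stopifnot(nTrill >= 3L, noteDuration > 0, interNoteGap >= 0,
            freqJitterSd >= 0, durationJitterSd >= 0, ampJitterSd >= 0,
            noiseLevel >= 0, rate > 0)
  structure(list(nIntro = as.integer(nIntro), nTrill = as.integer(nTrill),
                 noteDuration = noteDuration, interNoteGap = interNoteGap,
                 f0 = f0, sweep = sweep, introMultiplier = introMultiplier,
                 freqJitterSd = freqJitterSd,
                 durationJitterSd = durationJitterSd,
                 ampJitterSd = ampJitterSd, noiseLevel = noiseLevel,
                 rate = rate), class = "synthSongConfig")
}

#' Synthesize one note
#'
#' A frequency-swept sinusoid with per-note jitter drawn from the
#' current RNG stream: frequency `f0 + N(0, freqJitterSd)`, duration
#' `noteDuration + N(0, durationJitterSd)` truncated at 25% of nominal,
#' raised-cosine onset/offset ramps (10% of the note each), relative
#' amplitude `1 + N(0, ampJitterSd)`, plus white noise at `noiseLevel`
#' times the tone RMS.
#'
#' @param config a [synthSongConfig()].
#' @param f0 centre frequency before jitter; defaults to `config$f0`.
#' @return An [AudioClip-class].
#' @export
synthNote <- function(config, f0 = config$f0) {
  f <- f0 + stats::rnorm(1L, 0, config$freqJitterSd)
  d <- config$noteDuration + stats::rnorm(1L, 0, config$durationJitterSd)
  d <- max(d, 0.25 * config$noteDuration)
  n <- max(8L, round(d * config$rate))
  t <- (seq_len(n) - 1L) / config$rate
  amp <- 0.7 * max(0.05, 1 + stats::rnorm(1L, 0, config$ampJitterSd))
  x <- amp * sin(2 * pi * (f * t + config$sweep * t^2 / 2))
  nr <- max(1L, round(0.1 * n))
  ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 0.5) / nr)
  x[seq_len(nr)] <- x[seq_len(nr)] * ramp
  x[n + 1L - seq_len(nr)] <- x[n + 1L - seq_len(nr)] * ramp
  if (config$noiseLevel > 0)
    x <- x + stats::rnorm(n, 0, config$noiseLevel * rmsLevel(x))
  AudioClip(pmin(pmax(x, -1), 1), config$rate)
}

#' Synthesize an annotated song
#'
#' Renders `nIntro` introductory notes (at `introMultiplier` times the
#' trill frequency) followed by `nTrill` trill notes, all with per-note
#' jitter, and emits note annotations that align with the rendered audio
#' to the sample. With all jitters and noise at zero the trill notes are
#' bit-identical and the measured vocal consistency is 1.
#'
#' @param config a [synthSongConfig()].
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param songId,maleId,songType,context,timestamp metadata for the
#'   returned song.
#' @param positionJitter optional vector of per-trill-note frequency
#'   jitter SDs overriding `config$freqJitterSd` (used by the warm-up
#'   calibration).
#' @return An [AnnotatedSong-class] with audio and exact annotations;
#'   `trillIndex` is `nIntro + 1`.
#' @examples
#' song <- synthSong(synthSongConfig(freqJitterSd = 0,
#'   durationJitterSd = 0, ampJitterSd = 0, noiseLevel = 0), seed = 1)
#' nrow(notes(song))
#' @export
synthSong <- function(config, seed = NULL, songId = "s1", maleId = "m1",
                      songType = "A", context = "dawn",
                      timestamp = as.POSIXct("2020-04-20 05:00:00",
                                             tz = "UTC"),
                      positionJitter = NULL) {
  withSeed(seed, {
    rate <- config$rate
    gapN <- round(config$interNoteGap * rate)
    pieces <- list()
    ann <- list()
    pos <- 0L
    addNote <- function(clip, label) {
      start <- pos / rate
      pieces[[length(pieces) + 1L]] <<- clip@samples
      ann[[length(ann) + 1L]] <<- data.frame(
        start = start, end = (pos + length(clip@samples)) / rate,
        label = label, stringsAsFactors = FALSE)
      pos <<- pos + length(clip@samples)
      if (gapN > 0L) {
        pieces[[length(pieces) + 1L]] <<- numeric(gapN)
        pos <<- pos + gapN
      }
    }
    for (i in seq_len(config$nIntro))
      addNote(synthNote(config, f0 = config$f0 * config$introMultiplier),
              "intro")
    for (i in seq_len(config$nTrill)) {
      cfg <- config
      if (!is.null(positionJitter))
        cfg$freqJitterSd <- positionJitter[min(i, length(positionJitter))]
      addNote(synthNote(cfg), "trill")
    }
    clip <- AudioClip(unlist(pieces), rate)
    AnnotatedSong(songId = songId, maleId = maleId, timestamp = timestamp,
                  context = context, songType = songType, clip = clip,
                  notes = do.call(rbind, ann),
                  trillIndex = config$nIntro + 1L)
  })
}

meanConsistencyAtJitter <- function(config, jitter, nSongs, ...) {
  mean(vapply(seq_len(nSongs), function(i) {
    cfg <- config
    cfg$freqJitterSd <- jitter
    songScore(songConsistencyFromSong(synthSong(cfg), ...))
  }, numeric(1)))
}

#' Calibrate a declining-jitter schedule for a target warm-up slope
#'
#' The warm-up effect is injected into synthetic dawn sessions by
#' reducing the per-note frequency jitter across repetitions, because
#' vocal consistency is a derived measurement that cannot be set
#' directly. This routine probes the mapping from frequency-jitter SD to
#' expected song consistency by Monte Carlo, then inverts it so that the
#' expected consistency rises by approximately `slope` per repetition
#' starting from the config's base jitter.
#'
#' @param config a [synthSongConfig()].
#' @param slope target consistency increase per repetition.
#' @param nPositions number of repetition positions to cover.
#' @param probeLevels jitter SDs probed (default: 5 levels from 0 to the
#'   config's base jitter).
#' @param nProbe songs per probe level (default 10).
#' @param seed seed for the probe simulations.
#' @return numeric vector of length `nPositions`: the jitter SD to use
#'   at each repetition position.
#' @export
calibrateWarmupJitter <- function(config, slope, nPositions = 15L,
                                  probeLevels = NULL, nProbe = 10L,
                                  seed = 1L) {
  if (is.null(probeLevels))
    probeLevels <- seq(0, config$freqJitterSd, length.out = 5L)
  cons <- withSeed(seed, vapply(probeLevels, function(j)
    meanConsistencyAtJitter(config, j, nProbe), numeric(1)))
  # enforce a monotone (decreasing in jitter) probe curve for inversion
  consMono <- rev(cummax(rev(cons)))
  c1 <- consMono[length(consMono)]  # expected consistency at base jitter
  target <- c1 + slope * (seq_len(nPositions) - 1L)
  target <- pmin(target, max(consMono))
  stats::approx(x = consMono, y = probeLevels, xout = target,
                ties = "ordered", rule = 2)$y
}

#' Synthesize a dawn-song session with known bout structure
#'
#' Generates a string of song-type bouts the way a male sings at dawn:
#' each bout repeats one song type; consecutive bouts are separated
#' either by a silent pause longer than one minute (same or different
#' type) or by an immediate type switch during continuous singing. The
#' ground-truth table records every bout boundary and its trigger, so
#' downstream segmentation can be verified exactly. An optional warm-up
#' slope is injected through a calibrated declining-jitter schedule.
#'
#' @param songTypes named list of [synthSongConfig()]s, one per song
#'   type.
#' @param boutTypes character vector: song type of each bout.
#' @param boutLengths integer vector: songs per bout.
#' @param pauseBetweenBouts silent pause (seconds) inserted before a
#'   bout of the same type as its predecessor; must exceed 60 so the
#'   boundary is encoded as a silence gap.
#' @param interSongGap gap between consecutive songs within continuous
#'   singing, seconds (default 3).
#' @param warmupSlope target consistency increase per repetition
#'   (default 0: no warm-up).
#' @param seed integer seed.
#' @param maleId male identifier.
#' @param sessionStart POSIXct start of the session.
#' @return list with `songs` (list of [AnnotatedSong-class]),
#'   `songTable` (data.frame ready for [segmentBouts()]), `groundTruth`
#'   (data.frame: boutId, songType, nSongs, precededBy) and
#'   `jitterSchedules` (per-type calibrated jitter, when warm-up is on).
#' @export
synthDawnSession <- function(songTypes, boutTypes, boutLengths,
                             pauseBetweenBouts = 90, interSongGap = 3,
                             warmupSlope = 0, seed = 1L, maleId = "m1",
                             sessionStart = as.POSIXct(
                               "2020-04-20 04:30:00", tz = "UTC")) {
  stopifnot(length(boutTypes) == length(boutLengths),
            all(boutTypes %in% names(songTypes)))
  if (pauseBetweenBouts <= 60)
    stop("pauseBetweenBouts must exceed 60 s to encode a silence-gap ",
         "bout boundary")
  jitterSchedules <- NULL
  if (warmupSlope != 0) {
    jitterSchedules <- lapply(songTypes, calibrateWarmupJitter,
                              slope = warmupSlope,
                              nPositions = max(boutLengths), seed = seed)
  }
  withSeed(seed, {
    songs <- list()
    rows <- list()
    gt <- list()
    t0 <- 0
    sid <- 0L
    prevType <- NULL
    for (b in seq_along(boutTypes)) {
      tp <- boutTypes[b]
      preceded <- if (b == 1L) "session_start"
                  else if (identical(prevType, tp)) "silence_gap"
                  else "type_switch"
      if (b > 1L)
        t0 <- t0 + if (preceded == "silence_gap") pauseBetweenBouts
                   else interSongGap
      for (p in seq_len(boutLengths[b])) {
        sid <- sid + 1L
        id <- sprintf("%s_s%03d", maleId, sid)
        song <- synthSong(songTypes[[tp]], songId = id, maleId = maleId,
                          songType = tp,
                          timestamp = sessionStart + t0,
                          positionJitter = if (is.null(jitterSchedules))
                            NULL else jitterSchedules[[tp]][p],
                          context = "dawn")
        songs[[id]] <- song
        rows[[sid]] <- data.frame(songId = id, maleId = maleId,
                                  start = t0,
                                  duration = duration(song@clip),
                                  songType = tp, stringsAsFactors = FALSE)
        t0 <- t0 + duration(song@clip) + interSongGap
      }
      t0 <- t0 - interSongGap  # gap after last song handled at next bout
      gt[[b]] <- data.frame(boutId = sprintf("%s_b%02d", maleId, b),
                            songType = tp, nSongs = boutLengths[b],
                            precededBy = preceded, stringsAsFactors = FALSE)
      prevType <- tp
    }
    list(songs = songs, songTable = do.call(rbind, rows),
         groundTruth = do.call(rbind, gt),
         jitterSchedules = jitterSchedules)
  })
}

#' Simulate the Table-2-style warm-up generating process
#'
#' Numeric-level generator for the within-bout warm-up effect: per-song
#' vocal consistency is a baseline plus an individual random intercept,
#' a linear per-repetition increment, and residual noise. The returned
#' table also carries the within-bout standardized series (consistency
#' minus the first-song value), the response modelled by
#' [warmupTrend()].
#'
#' @param slope consistency increase per repetition (default 0.002).
#' @param residualSd residual SD of per-song consistency
#'   (default 0.074).
#' @param individualSd SD of the per-individual intercept
#'   (default 0.028).
#' @param baseline mean consistency of a first song (default 0.8).
#' @param nIndividuals number of males (default 18).
#' @param boutsPerIndividual bouts per male (default 4).
#' @param positions repetitions per bout (default 15).
#' @param seed integer seed.
#' @return data.frame with columns `maleId`, `boutId`, `position`,
#'   `consistency`, `stdConsistency`.
#' @export
simulateWarmup <- function(slope = 0.002, residualSd = 0.074,
                           individualSd = 0.028, baseline = 0.8,
                           nIndividuals = 18L, boutsPerIndividual = 4L,
                           positions = 15L, seed = NULL) {
  withSeed(seed, {
    out <- list()
    for (i in seq_len(nIndividuals)) {
      bi <- stats::rnorm(1L, 0, individualSd)
      for (b in seq_len(boutsPerIndividual)) {
        p <- seq_len(positions)
        cons <- baseline + bi + slope * p +
          stats::rnorm(positions, 0, residualSd)
        out[[length(out) + 1L]] <- data.frame(
          maleId = sprintf("m%02d", i),
          boutId = sprintf("m%02d_b%02d", i, b), position = p,
          consistency = cons, stdConsistency = cons - cons[1L],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate binary female responses from the habituation process
#'
#' Generates per-song binary responses under the logistic habituation/
#' dishabituation model: for female `f` with random intercept
#' `b_f ~ N(0, femaleSd^2)`, the response probability at position `p`
#' of a bout is `inverseLogit(intercept + b_f + betaSwitch*s +
#' betaLogPos*z(p) + betaInteraction*s*z(p))` where `s` indicates a
#' switch-preceded bout and `z` is the centred/scaled log position
#' ([scaledLogPosition()]) — the same convention the fitter uses, so
#' recovery is exact in expectation. Coefficient defaults are the
#' fitted habituation model of the playback experiment. Bouts alternate
#' between silence-preceded and switch-preceded in equal numbers.
#'
#' @param intercept,betaSwitch,betaLogPos,betaInteraction logit-scale
#'   coefficients (defaults 0.052, -0.813, -1.039, 0.532).
#' @param femaleSd SD of the female random intercept (default 0.87).
#' @param nFemales,boutsPerFemale,positionsPerBout design size
#'   (defaults 100, 8, 15).
#' @param seed integer seed.
#' @return data.frame with columns `femaleId`, `boutIndex`,
#'   `precededBy`, `position`, `response` — the input shape of
#'   [fitHabituationModel()].
#' @export
simulateResponses <- function(intercept = 0.052, betaSwitch = -0.813,
                              betaLogPos = -1.039,
                              betaInteraction = 0.532, femaleSd = 0.87,
                              nFemales = 100L, boutsPerFemale = 8L,
                              positionsPerBout = 15L, seed = NULL) {
  stopifnot(positionsPerBout >= 1L, femaleSd >= 0)
  withSeed(seed, {
    boutKind <- rep(c("silence_gap", "type_switch"),
                    length.out = boutsPerFemale)
    d <- expand.grid(position = seq_len(positionsPerBout),
                     boutIndex = seq_len(boutsPerFemale),
                     femaleId = sprintf("f%03d", seq_len(nFemales)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d$precededBy <- boutKind[d$boutIndex]
    b <- stats::rnorm(nFemales, 0, femaleSd)
    names(b) <- sprintf("f%03d", seq_len(nFemales))
    s <- as.integer(d$precededBy == "type_switch")
    z <- scaledLogPosition(d$position)
    eta <- intercept + b[d$femaleId] + betaSwitch * s + betaLogPos * z +
      betaInteraction * s * z
    d$response <- stats::rbinom(nrow(d), 1L, inverseLogit(eta))
    d[, c("femaleId", "boutIndex", "precededBy", "position", "response")]
  })
}
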