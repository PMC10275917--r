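#' Build a 75-second song-type bout from one exemplar song
#'
#' Repeats a single exemplar song at the male's measured natural song
#' rate for a fixed bout duration: onsets fall at 0, 60/rate, 120/rate,
#' ... while the whole song still fits inside the bout; the remainder is
#' padded with silence so the bout lasts exactly `boutDuration` seconds.
#'
#' @param song an [AudioClip-class], one exemplar song.
#' @param measuredRate the song rate measured from the male's natural
#'   singing, songs per minute (> 0).
#' @param boutDuration bout length in seconds (default 75, i.e. 1:15).
#' @return list with `clip` (the rendered [AudioClip-class], exactly
#'   `boutDuration` s) and `onsets` (numeric vector of song onset times
#'   in seconds from bout start).
#' @examples
#' song <- AudioClip(sin(2 * pi * 440 * (0:7999) / 4000), 4000)
#' b <- buildSongTypeBout(song, measuredRate = 8)
#' length(b$onsets) # 10 onsets: 0, 7.5, ..., 67.5
#' @export
buildSongTypeBout <- function(song, measuredRate, boutDuration = 75) {
  stopifnot(is(song, "AudioClip"))
  if (measuredRate <= 0) stop("measuredRate must be positive")
  ioi <- 60 / measuredRate
  dur <- duration(song)
  if (dur > ioi)
    stop("song (", round(dur, 3), " s) is longer than the inter-onset ",
         "interval 60/rate = ", round(ioi, 3), " s")
  onsets <- seq(0, boutDuration, by = ioi)
  onsets <- onsets[onsets + dur <= boutDuration]
  out <- numeric(round(boutDuration * song@rate))
  ns <- length(song@samples)
  for (t in onsets) {
    i0 <- round(t * song@rate)
    out[(i0 + 1L):(i0 + ns)] <- song@samples
  }
  list(clip = AudioClip(out, song@rate), onsets = onsets)
}

#' Build the randomized dual-song-type playback schedule
#'
#' Constructs the timed structure of one 1-hour playback trial: after a
#' leading silence of at least 5 minutes, 12 playback rounds of 5
#' minutes each. Every round holds one 150 s song section — two 75 s
#' song-type bouts, one of each song type, in seeded random order — and
#' one 150 s silence section; whether song or silence comes first is an
#' independent seeded draw per round. The whole schedule (24 song-type
#' bouts, 12 song and 12 silence sections) is a pure function of its
#' arguments.
#'
#' @param typeA,typeB the two (distinct) song-type labels.
#' @param seed integer seed for the order randomization.
#' @param leadSilence leading silence in seconds (>= 300).
#' @param boutDuration song-type bout duration in seconds (default 75).
#' @param nRounds number of playback rounds (default 12).
#' @return A [PlaybackSchedule-class].
#' @examples
#' sched <- buildSchedule("A", "B", seed = 1)
#' sum(segments(sched)$kind == "song") # 24 song-type bouts
#' @export
buildSchedule <- function(typeA, typeB, seed, leadSilence = 300,
                          boutDuration = 75, nRounds = 12L) {
  if (identical(typeA, typeB)) stop("the two song types must be distinct")
  if (leadSilence < 300) stop("leading silence must be at least 300 s")
  seed <- as.integer(seed)
  silenceDuration <- 2 * boutDuration
  songFirst <- withSeed(seed, stats::runif(nRounds) < 0.5)
  aFirst <- withSeed(seed + 1L, stats::runif(nRounds) < 0.5)

  rows <- list(data.frame(round = 0L, kind = "silence",
                          songType = NA_character_, start = 0,
                          duration = leadSilence, stringsAsFactors = FALSE))
  t <- leadSilence
  for (r in seq_len(nRounds)) {
    types <- if (aFirst[r]) c(typeA, typeB) else c(typeB, typeA)
    songRows <- data.frame(round = r, kind = "song", songType = types,
                           start = NA_real_, duration = boutDuration,
                           stringsAsFactors = FALSE)
    silRow <- data.frame(round = r, kind = "silence",
                         songType = NA_character_, start = NA_real_,
                         duration = silenceDuration, stringsAsFactors = FALSE)
    block <- if (songFirst[r]) rbind(songRows, silRow)
             else rbind(silRow, songRows)
    block$start <- t + cumsum(c(0, block$duration[-nrow(block)]))
    t <- t + sum(block$duration)
    rows[[length(rows) + 1L]] <- block
  }
  segs <- do.call(rbind, rows)
  rownames(segs) <- NULL
  new("PlaybackSchedule", segments = segs, seed = seed,
      leadSilence = leadSilence)
}

#' Render a playback schedule to audio with a cue table
#'
#' Renders the stimulus waveform (song-type bouts built with
#' [buildSongTypeBout()] at each type's measured song rate, silence
#' elsewhere) and peak-normalizes it to a configured digital level — the
#' digital counterpart of calibrating speaker output level in the field.
#' The cue table lists every song onset with its position index within
#' its song-type bout, the alignment key for response scoring.
#'
#' @param schedule a [PlaybackSchedule-class].
#' @param clips named list of exemplar [AudioClip-class]s, one per song
#'   type appearing in the schedule.
#' @param measuredRates named numeric vector of song rates (songs per
#'   minute) keyed by song type.
#' @param analysisRate output sampling rate in Hz; clips at other rates
#'   are resampled with a warning.
#' @param peakDb digital peak level in dBFS (default -3).
#' @return list with `clip` (the rendered [AudioClip-class]) and `cues`
#'   (data.frame: `boutIndex`, `songType`, `precededBy`, `position`,
#'   `time` in seconds from trial start, `boutStart`, `boutEnd`).
#' @export
renderSchedule <- function(schedule, clips, measuredRates,
                           analysisRate = 48000, peakDb = -3) {
  stopifnot(is(schedule, "PlaybackSchedule"))
  segs <- schedule@segments
  types <- unique(segs$songType[segs$kind == "song"])
  if (!all(types %in% names(clips)) || !all(types %in% names(measuredRates)))
    stop("clips and measuredRates must cover song types: ",
         paste(types, collapse = ", "))
  bouts <- list()
  for (tp in types) {
    clip <- clips[[tp]]
    if (clip@rate != analysisRate) {
      warning("resampling song type ", tp, " from ", clip@rate, " to ",
              analysisRate, " Hz")
      clip <- resampleClip(clip, analysisRate)
    }
    bouts[[tp]] <- buildSongTypeBout(clip, measuredRates[[tp]],
                                     boutDuration = segs$duration[
                                       segs$kind == "song"][1L])
  }
  total <- round((segs$start[nrow(segs)] + segs$duration[nrow(segs)]) *
                   analysisRate)
  out <- numeric(total)
  cues <- list()
  boutIndex <- 0L
  for (i in seq_len(nrow(segs))) {
    if (segs$kind[i] != "song") next
    boutIndex <- boutIndex + 1L
    tp <- segs$songType[i]
    b <- bouts[[tp]]
    i0 <- round(segs$start[i] * analysisRate)
    out[(i0 + 1L):(i0 + length(b$clip@samples))] <- b$clip@samples
    preceded <- if (i > 1L && segs$kind[i - 1L] == "song") "type_switch"
                else "silence_gap"
    cues[[boutIndex]] <- data.frame(
      boutIndex = boutIndex, songType = tp, precededBy = preceded,
      position = seq_along(b$onsets), time = segs$start[i] + b$onsets,
      boutStart = segs$start[i], boutEnd = segs$start[i] + segs$duration[i],
      stringsAsFactors = FALSE)
  }
  peak <- max(abs(out))
  if (peak > 0) out <- out * (10^(peakDb / 20) / peak)
  list(clip = AudioClip(out, analysisRate), cues = do.call(rbind, cues))
}
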