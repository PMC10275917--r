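#' @import methods
NULL

#' AudioClip: a mono waveform with its sampling rate
#'
#' Minimal container for audio passed between the I/O, spectrogram and
#' playback-rendering functions. Samples are dimensionless amplitudes in
#' \[-1, 1\]; the rate is in Hz.
#'
#' @slot samples numeric vector of waveform samples.
#' @slot rate sampling rate in samples per second.
#'
#' @seealso [readWav()], [sliceNote()], [spectrogram()]
#' @export
setClass("AudioClip",
  representation(samples = "numeric", rate = "numeric"))

setValidity("AudioClip", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive finite number")
  if (length(object@samples) == 0L)
    msg <- c(msg, "samples must be non-empty")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (length(msg)) msg else TRUE
})

setClassUnion("AudioClipOrNULL", c("AudioClip", "NULL"))

#' Construct an AudioClip
#'
#' @param samples numeric waveform, amplitudes in \[-1, 1\].
#' @param rate sampling rate (Hz).
#' @return An [AudioClip-class] object.
#' @examples
#' clip <- AudioClip(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration(clip)
#' @export
AudioClip <- function(samples, rate) {
  new("AudioClip", samples = as.numeric(samples), rate = as.numeric(rate))
}

#' SpectrogramMatrix: an STFT magnitude matrix
#'
#' Frequency-bin by time-frame matrix of non-negative linear magnitudes,
#' together with the grid steps needed to interpret it.
#'
#' @slot values numeric matrix, rows = frequency bins, columns = time frames.
#' @slot frameStep seconds between successive frames (hop / rate).
#' @slot freqStep Hz per frequency bin (rate / window).
#' @export
setClass("SpectrogramMatrix",
  representation(values = "matrix", frameStep = "numeric", freqStep = "numeric"))

setValidity("SpectrogramMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (length(object@frameStep) != 1L || object@frameStep <= 0)
    msg <- c(msg, "frameStep must be a single positive number")
  if (length(object@freqStep) != 1L || object@freqStep <= 0)
    msg <- c(msg, "freqStep must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' AnnotatedSong: one song with its note annotations and metadata
#'
#' A song is a few introductory notes followed by a trill, the terminal
#' section in which one note type is repeated. Notes are stored as a
#' data.frame with columns `start`, `end` (seconds from clip start) and
#' `label`; all notes from `trillIndex` onwards belong to the trill.
#'
#' @slot songId character identifier.
#' @slot maleId identifier of the singing male.
#' @slot timestamp POSIXct time of the song (start).
#' @slot context `"dawn"` or `"daytime"`.
#' @slot songType categorical song-type label.
#' @slot clip the audio ([AudioClip-class]) or `NULL` when only timing
#'   metadata is carried (e.g. bout segmentation).
#' @slot notes data.frame of note segments ordered by start time.
#' @slot trillIndex integer, 1-based index of the first trill note.
#'
#' @export
setClass("AnnotatedSong",
  representation(songId = "character", maleId = "character",
    timestamp = "POSIXct", context = "character", songType = "character",
    clip = "AudioClipOrNULL", notes = "data.frame", trillIndex = "integer"))

setValidity("AnnotatedSong", function(object) {
  msg <- character()
  n <- object@notes
  if (nrow(n)) {
    if (!all(c("start", "end", "label") %in% names(n)))
      msg <- c(msg, "notes must have columns start, end, label")
    else {
      if (any(n$start >= n$end)) msg <- c(msg, "every note needs start < end")
      if (is.unsorted(n$start)) msg <- c(msg, "notes must be ordered by start")
      if (nrow(n) > 1L && any(n$start[-1L] < n$end[-nrow(n)] - 1e-9))
        msg <- c(msg, "notes must not overlap")
      if (!is.null(object@clip) && any(n$end > duration(object@clip) + 1e-9))
        msg <- c(msg, "notes must lie within the clip")
    }
  }
  if (length(object@trillIndex) != 1L || is.na(object@trillIndex) ||
      object@trillIndex < 1L || (nrow(n) && object@trillIndex > nrow(n)))
    msg <- c(msg, "trillIndex must point at a note")
  if (!object@context %in% c("dawn", "daytime"))
    msg <- c(msg, "context must be 'dawn' or 'daytime'")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedSong
#'
#' @param songId,maleId,songType character identifiers.
#' @param timestamp POSIXct song start time.
#' @param context `"dawn"` or `"daytime"`.
#' @param clip [AudioClip-class] or `NULL`.
#' @param notes data.frame with columns `start`, `end`, `label`.
#' @param trillIndex 1-based index of the first trill note.
#' @return An [AnnotatedSong-class].
#' @export
AnnotatedSong <- function(songId, maleId, timestamp, context, songType,
                          clip = NULL, notes = data.frame(), trillIndex = 1L) {
  new("AnnotatedSong", songId = as.character(songId),
      maleId = as.character(maleId), timestamp = as.POSIXct(timestamp),
      context = context, songType = as.character(songType), clip = clip,
      notes = notes, trillIndex = as.integer(trillIndex))
}

#' ConsistencyResult: pairwise SPCC scores and the song-level score
#'
#' Holds the symmetric matrix of pairwise spectrogram cross-correlation
#' scores among trill notes, the per-note means (each note against all
#' others) and the song-level vocal consistency (mean of the note scores,
#' which for a symmetric matrix equals the mean over unordered pairs).
#'
#' @slot pairMatrix symmetric n x n matrix of SPCC scores in \[-1, 1\],
#'   unit diagonal.
#' @slot noteScores per-note mean of off-diagonal row entries.
#' @slot songScore song-level vocal consistency.
#' @export
setClass("ConsistencyResult",
  representation(pairMatrix = "matrix", noteScores = "numeric",
                 songScore = "numeric"))

setValidity("ConsistencyResult", function(object) {
  m <- object@pairMatrix
  msg <- character()
  if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8))
    msg <- c(msg, "pairMatrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-8))
    msg <- c(msg, "pairMatrix diagonal must be 1")
  if (any(abs(m) > 1 + 1e-8))
    msg <- c(msg, "scores must lie in [-1, 1]")
  if (length(object@noteScores) != nrow(m))
    msg <- c(msg, "one noteScore per note")
  if (length(msg)) msg else TRUE
})

#' SongTypeBout: a run of consecutive same-type songs
#'
#' A song-type bout is a run of at least three consecutive renditions of
#' one song type, terminated by a switch to another type or by a silent
#' pause longer than one minute. Shorter runs are retained but flagged
#' sub-minimal so that totals stay auditable.
#'
#' @slot boutId character identifier.
#' @slot maleId identifier of the male.
#' @slot songType song type of every song in the bout.
#' @slot songs data.frame of the member songs in order (columns include
#'   `songId`, `start`, `duration`, `position`).
#' @slot precededBy `"session_start"`, `"silence_gap"` or `"type_switch"`.
#' @slot subMinimal `TRUE` for runs of fewer than three songs.
#' @export
setClass("SongTypeBout",
  representation(boutId = "character", maleId = "character",
    songType = "character", songs = "data.frame", precededBy = "character",
    subMinimal = "logical"))

setValidity("SongTypeBout", function(object) {
  msg <- character()
  if (!object@precededBy %in% c("session_start", "silence_gap", "type_switch"))
    msg <- c(msg, "invalid precededBy")
  if (!object@subMinimal && nrow(object@songs) < 3L)
    msg <- c(msg, "a valid bout has at least three songs")
  if (length(msg)) msg else TRUE
})

#' PlaybackSchedule: the timed structure of one playback trial
#'
#' Twelve 5-minute rounds follow a leading silence; each round holds one
#' 150 s song section (two 75 s song-type bouts) and one 150 s silence
#' section in seeded random order, 24 song-type bouts in total.
#'
#' @slot segments data.frame with columns `round`, `kind` (`"song"` or
#'   `"silence"`), `songType` (`NA` for silence), `start`, `duration`
#'   (seconds from trial start). Round 0 is the leading silence.
#' @slot seed integer seed the schedule was drawn with.
#' @slot leadSilence leading silence duration in seconds (>= 300).
#' @export
setClass("PlaybackSchedule",
  representation(segments = "data.frame", seed = "integer",
                 leadSilence = "numeric"))

setValidity("PlaybackSchedule", function(object) {
  s <- object@segments
  msg <- character()
  if (!all(c("round", "kind", "songType", "start", "duration") %in% names(s)))
    msg <- c(msg, "segments missing required columns")
  else {
    if (any(s$duration <= 0)) msg <- c(msg, "durations must be positive")
    if (nrow(s) > 1L &&
        any(abs(s$start[-1L] - (s$start[-nrow(s)] + s$duration[-nrow(s)])) > 1e-9))
      msg <- c(msg, "segments must be contiguous and non-overlapping")
    if (sum(s$kind == "song") != 24L)
      msg <- c(msg, "a schedule holds 24 song-type bouts")
    if (any(s$kind == "song" & is.na(s$songType)))
      msg <- c(msg, "song segments must carry a song type")
  }
  if (object@leadSilence < 300)
    msg <- c(msg, "leading silence must be at least 300 s")
  if (length(msg)) msg else TRUE
})
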