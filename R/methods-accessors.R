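#' @rdname AudioClip-class
setMethod("samples", "AudioClip", function(x) x@samples)

#' @rdname AudioClip-class
setMethod("sampleRate", "AudioClip", function(x) x@rate)

#' @rdname AudioClip-class
setMethod("duration", "AudioClip", function(x) length(x@samples) / x@rate)

setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip: %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(object@samples), object@rate,
              duration(object), max(abs(object@samples))))
})

#' @rdname AnnotatedSong-class
setMethod("notes", "AnnotatedSong", function(x) x@notes)

#' @rdname AnnotatedSong-class
setMethod("trillIndex", "AnnotatedSong", function(x) x@trillIndex)

#' @rdname AnnotatedSong-class
setMethod("songType", "AnnotatedSong", function(x) x@songType)

#' @rdname AnnotatedSong-class
setMethod("maleId", "AnnotatedSong", function(x) x@maleId)

#' @rdname AnnotatedSong-class
setMethod("songId", "AnnotatedSong", function(x) x@songId)

#' @rdname trillNotes
setMethod("trillNotes", "AnnotatedSong", function(x) {
  if (nrow(x@notes) == 0L) return(x@notes)
  x@notes[seq(x@trillIndex, nrow(x@notes)), , drop = FALSE]
})

setMethod("show", "AnnotatedSong", function(object) {
  nTrill <- if (nrow(object@notes)) nrow(object@notes) - object@trillIndex + 1L else 0L
  cat(sprintf("AnnotatedSong %s: male %s, type %s, %s, %d notes (%d trill)\n",
              object@songId, object@maleId, object@songType, object@context,
              nrow(object@notes), nTrill))
})

#' @rdname ConsistencyResult-class
setMethod("pairMatrix", "ConsistencyResult", function(x) x@pairMatrix)

#' @rdname ConsistencyResult-class
setMethod("noteScores", "ConsistencyResult", function(x) x@noteScores)

#' @rdname ConsistencyResult-class
setMethod("songScore", "ConsistencyResult", function(x) x@songScore)

setMethod("show", "ConsistencyResult", function(object) {
  cat(sprintf("ConsistencyResult: %d trill notes, vocal consistency %.4f\n",
              nrow(object@pairMatrix), object@songScore))
})

#' @rdname SongTypeBout-class
setMethod("precededBy", "SongTypeBout", function(x) x@precededBy)

#' @rdname SongTypeBout-class
setMethod("boutSongs", "SongTypeBout", function(x) x@songs)

#' @rdname SongTypeBout-class
setMethod("isSubMinimal", "SongTypeBout", function(x) x@subMinimal)

#' @rdname SongTypeBout-class
setMethod("songType", "SongTypeBout", function(x) x@songType)

#' @rdname SongTypeBout-class
setMethod("maleId", "SongTypeBout", function(x) x@maleId)

setMethod("show", "SongTypeBout", function(object) {
  cat(sprintf("SongTypeBout %s: male %s, type %s, %d songs, preceded by %s%s\n",
              object@boutId, object@maleId, object@songType,
              nrow(object@songs), object@precededBy,
              if (object@subMinimal) " [sub-minimal]" else ""))
})

#' @rdname PlaybackSchedule-class
setMethod("segments", "PlaybackSchedule", function(x) x@segments)

#' @rdname PlaybackSchedule-class
setMethod("duration", "PlaybackSchedule", function(x) {
  s <- x@segments
  s$start[nrow(s)] + s$duration[nrow(s)]
})

setMethod("show", "PlaybackSchedule", function(object) {
  s <- object@segments
  cat(sprintf(paste0("PlaybackSchedule: lead silence %g s + %d rounds, ",
                     "%d song-type bouts, total %g s (seed %d)\n"),
              object@leadSilence, max(s$round), sum(s$kind == "song"),
              duration(object), object@seed))
})
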