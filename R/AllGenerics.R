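#' @rdname AudioClip-class
#' @param object,x an object.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname AudioClip-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname AudioClip-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname AnnotatedSong-class
#' @export
setGeneric("notes", function(x) standardGeneric("notes"))

#' @rdname AnnotatedSong-class
#' @export
setGeneric("trillIndex", function(x) standardGeneric("trillIndex"))

#' @rdname AnnotatedSong-class
#' @export
setGeneric("songType", function(x) standardGeneric("songType"))

#' @rdname AnnotatedSong-class
#' @export
setGeneric("maleId", function(x) standardGeneric("maleId"))

#' @rdname AnnotatedSong-class
#' @export
setGeneric("songId", function(x) standardGeneric("songId"))

#' Trill notes of a song
#'
#' Returns the note table of the trill section (all notes from
#' `trillIndex` onwards), the section on which vocal consistency is
#' measured.
#' @param x an [AnnotatedSong-class].
#' @return data.frame of trill note segments.
#' @export
setGeneric("trillNotes", function(x) standardGeneric("trillNotes"))

#' @rdname ConsistencyResult-class
#' @param x an object.
#' @export
setGeneric("pairMatrix", function(x) standardGeneric("pairMatrix"))

#' @rdname ConsistencyResult-class
#' @export
setGeneric("noteScores", function(x) standardGeneric("noteScores"))

#' @rdname ConsistencyResult-class
#' @export
setGeneric("songScore", function(x) standardGeneric("songScore"))

#' @rdname SongTypeBout-class
#' @param x an object.
#' @export
setGeneric("precededBy", function(x) standardGeneric("precededBy"))

#' @rdname SongTypeBout-class
#' @export
setGeneric("boutSongs", function(x) standardGeneric("boutSongs"))

#' @rdname SongTypeBout-class
#' @export
setGeneric("isSubMinimal", function(x) standardGeneric("isSubMinimal"))

#' @rdname PlaybackSchedule-class
#' @param x an object.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
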