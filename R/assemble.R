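#' Assemble AnnotatedSong objects from clips, label tracks and metadata
#'
#' Joins one audio clip and one note label track per song with the song
#' metadata table. The trill is identified from the note labels: all
#' notes carrying `trillLabel` form the trill, which must be the terminal
#' section of the song. Songs whose trill has fewer than two notes are
#' kept but flagged ineligible for consistency analysis (pairwise
#' similarity is undefined on fewer than one pair), mirroring the removal
#' of song types with very short trills from the field analysis.
#'
#' @param clips named list of [AudioClip-class], names are song ids.
#' @param labelTracks named list of note-segment data.frames (as returned
#'   by [readLabelTrack()]), names are song ids.
#' @param metadata data.frame with columns `song_id`, `male_id`,
#'   `timestamp` (ISO-8601), `context` (`dawn`/`daytime`), `song_type`.
#' @param trillLabel label marking trill notes (default `"trill"`).
#' @return list with `songs` (list of [AnnotatedSong-class], named by
#'   song id) and `consistencyEligible` (named logical: trill has >= 2
#'   notes).
#' @export
assembleSongs <- function(clips, labelTracks, metadata, trillLabel = "trill") {
  need <- c("song_id", "male_id", "timestamp", "context", "song_type")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  ids <- names(clips)
  if (is.null(ids) || is.null(names(labelTracks)))
    stop("clips and labelTracks must be named by song id")
  missingLabels <- setdiff(ids, names(labelTracks))
  if (length(missingLabels))
    stop("no label track for song id(s): ", paste(missingLabels, collapse = ", "))
  missingMeta <- setdiff(ids, metadata$song_id)
  if (length(missingMeta))
    stop("no metadata for song id(s): ", paste(missingMeta, collapse = ", "))

  songs <- vector("list", length(ids))
  eligible <- logical(length(ids))
  names(songs) <- names(eligible) <- ids
  for (id in ids) {
    seg <- labelTracks[[id]]
    md <- metadata[metadata$song_id == id, , drop = FALSE][1L, ]
    isTrill <- seg$label == trillLabel
    if (!any(isTrill))
      stop("song ", id, ": no note labelled '", trillLabel, "'")
    ti <- which(isTrill)[1L]
    if (!all(isTrill[ti:nrow(seg)]))
      stop("song ", id, ": trill notes must form the terminal section")
    songs[[id]] <- AnnotatedSong(
      songId = id, maleId = md$male_id,
      timestamp = as.POSIXct(md$timestamp, tz = "UTC"),
      context = md$context, songType = md$song_type,
      clip = clips[[id]], notes = seg, trillIndex = ti)
    eligible[id] <- sum(isTrill) >= 2L
  }
  if (any(!eligible))
    warning(sum(!eligible), " song(s) excluded from consistency analysis ",
            "(trill shorter than 2 notes): ",
            paste(ids[!eligible], collapse = ", "))
  list(songs = songs, consistencyEligible = eligible)
}
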