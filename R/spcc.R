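#' Spectrogram cross-correlation between two notes
#'
#' SPCC score of two magnitude spectrograms: the maximum, over bounded
#' temporal offsets, of the Pearson correlation between the two matrices
#' computed over their overlapping frame range (frequency x overlapping
#' time cells flattened). Candidate lags are the offsets
#' `seq(-maxOffset, maxOffset, by = offsetStep)` rounded to the nearest
#' whole frame and deduplicated — with a 512-sample window at 90% overlap
#' and 48 kHz the native hop is ~1.07 ms, the closest realizable version
#' of a 1 ms lag grid. Lags leaving fewer than `minOverlap` overlapping
#' frames are skipped.
#'
#' @param a,b [SpectrogramMatrix-class] objects on identical frequency
#'   and frame grids.
#' @param maxOffset maximum temporal offset searched, seconds
#'   (default 0.020).
#' @param offsetStep temporal resolution of the lag grid, seconds
#'   (default 0.001).
#' @param minOverlap minimum overlapping frames for a lag to count
#'   (default 3).
#' @return A score in \[-1, 1\]. A fully zero-variance comparison (e.g.
#'   silence against silence) returns 0 with a warning rather than NaN.
#' @export
spccPair <- function(a, b, maxOffset = 0.020, offsetStep = 0.001,
                     minOverlap = 3L) {
  stopifnot(is(a, "SpectrogramMatrix"), is(b, "SpectrogramMatrix"))
  if (abs(a@frameStep - b@frameStep) > 1e-12 ||
      abs(a@freqStep - b@freqStep) > 1e-12)
    stop("spectrograms must share the same frequency and frame grids")
  na <- ncol(a@values)
  nb <- ncol(b@values)
  lags <- unique(as.integer(round(
    seq(-maxOffset, maxOffset, by = offsetStep) / a@frameStep)))
  best <- -Inf
  anyVariance <- FALSE
  for (k in lags) {
    # frames i of a align with frames i - k of b
    lo <- max(1L, 1L + k)
    hi <- min(na, nb + k)
    if (hi - lo + 1L < minOverlap) next
    ia <- lo:hi
    ib <- ia - k
    va <- as.vector(a@values[, ia, drop = FALSE])
    vb <- as.vector(b@values[, ib, drop = FALSE])
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    anyVariance <- TRUE
    r <- stats::cor(va, vb)
    if (r > best) best <- r
  }
  if (!anyVariance) {
    warning("zero-variance overlap at every lag; SPCC defined as 0")
    return(0)
  }
  min(max(best, -1), 1)
}

#' Per-note consistency from a pairwise SPCC matrix
#'
#' The vocal consistency of one note is the mean SPCC score of all
#' pairwise comparisons between that note and every other note in the
#' trill, i.e. the mean of row `i` excluding the diagonal.
#'
#' @param pairMatrix symmetric matrix of pairwise SPCC scores.
#' @param i note index.
#' @return The mean off-diagonal score of row `i`.
#' @export
noteConsistency <- function(pairMatrix, i) {
  n <- nrow(pairMatrix)
  if (is.null(n) || n < 2L)
    stop("consistency is undefined for fewer than 2 notes")
  mean(pairMatrix[i, -i])
}

#' Vocal consistency of a song from its trill notes
#'
#' Computes every pairwise SPCC score among the trill notes, the
#' per-note means, and the song-level vocal consistency (mean of the
#' note scores; by symmetry this equals the mean over all unordered
#' note pairs). Notes are resampled to a common analysis rate and notes
#' shorter than one FFT window are zero-padded to one window.
#'
#' @param trillNotes list of [AudioClip-class], one per trill note, in
#'   order; at least two.
#' @param analysisRate common analysis rate in Hz (default 48000).
#' @param windowSamples,overlapFraction spectrogram parameters, see
#'   [spectrogram()].
#' @param maxOffset,offsetStep lag-search parameters, see [spccPair()].
#' @return A [ConsistencyResult-class].
#' @examples
#' note <- AudioClip(sin(2 * pi * 4000 * (0:2399) / 48000), 48000)
#' songScore(songConsistency(list(note, note, note)))
#' @export
songConsistency <- function(trillNotes, analysisRate = 48000,
                            windowSamples = 512L, overlapFraction = 0.9,
                            maxOffset = 0.020, offsetStep = 0.001) {
  n <- length(trillNotes)
  if (n < 2L) stop("consistency is undefined for fewer than 2 trill notes")
  specs <- lapply(trillNotes, function(clip) {
    stopifnot(is(clip, "AudioClip"))
    clip <- resampleClip(clip, analysisRate)
    clip <- padClip(clip, windowSamples)
    spectrogram(clip, windowSamples, overlapFraction)
  })
  m <- diag(nrow = n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- spccPair(specs[[i]], specs[[j]],
                                     maxOffset, offsetStep)
    }
  }
  scores <- vapply(seq_len(n), function(i) noteConsistency(m, i), numeric(1))
  new("ConsistencyResult", pairMatrix = m, noteScores = scores,
      songScore = mean(scores))
}

#' Vocal consistency of an AnnotatedSong
#'
#' Convenience wrapper: slices the trill notes out of the song's clip
#' and calls [songConsistency()].
#'
#' @param song an [AnnotatedSong-class] with audio.
#' @param ... passed to [songConsistency()].
#' @return A [ConsistencyResult-class].
#' @export
songConsistencyFromSong <- function(song, ...) {
  stopifnot(is(song, "AnnotatedSong"))
  if (is.null(song@clip)) stop("song carries no audio")
  tn <- trillNotes(song)
  clips <- lapply(seq_len(nrow(tn)), function(i)
    sliceNote(song@clip, tn$start[i], tn$end[i]))
  songConsistency(clips, analysisRate = song@clip@rate, ...)
}
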