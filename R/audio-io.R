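#' Read a PCM WAV file as a mono AudioClip
#'
#' Reads RIFF/WAVE files with 16- or 24-bit integer PCM encoding. Stereo
#' files are mixed down by channel averaging; integer samples are scaled
#' by 2^(bits-1) so full-scale negative maps to exactly -1.
#'
#' @param path path to a `.wav` file.
#' @return An [AudioClip-class].
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWav(AudioClip(sin(2 * pi * 440 * (0:799) / 8000), 8000), f)
#' readWav(f)
#' @export
readWav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  data <- NULL
  repeat {
    idRaw <- readBin(con, "raw", 4L)
    if (length(idRaw) < 4L) break
    id <- rawToChar(idRaw)
    size <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audioFormat = readBin(con, "integer", 1L, size = 2, endian = "little",
                              signed = FALSE),
        channels = readBin(con, "integer", 1L, size = 2, endian = "little",
                           signed = FALSE),
        rate = readBin(con, "integer", 1L, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1L, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1L, size = 2, endian = "little"))
      fmt$bits <- readBin(con, "integer", 1L, size = 2, endian = "little",
                          signed = FALSE)
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
      if (!is.null(fmt)) break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt or data chunk: ", path)
  if (fmt$audioFormat != 1L)
    stop("unsupported WAV encoding (only integer PCM): format tag ",
         fmt$audioFormat)
  if (!fmt$bits %in% c(16L, 24L))
    stop("unsupported bit depth: ", fmt$bits, " (expected 16 or 24)")
  x <- if (fmt$bits == 16L) {
    readBin(data, "integer", length(data) %/% 2L, size = 2, endian = "little",
            signed = TRUE) / 32768
  } else {
    n <- length(data) %/% 3L
    b <- matrix(as.integer(data[seq_len(3L * n)]), nrow = 3L)
    v <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  }
  if (fmt$channels > 1L) {
    n <- length(x) %/% fmt$channels
    x <- rowMeans(matrix(x[seq_len(n * fmt$channels)],
                         ncol = fmt$channels, byrow = TRUE))
  }
  AudioClip(x, fmt$rate)
}

#' Write an AudioClip as a 16-bit PCM mono WAV file
#'
#' @param clip an [AudioClip-class]; samples outside \[-1, 1\] are clipped.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWav <- function(clip, path) {
  stopifnot(is(clip, "AudioClip"))
  x <- pmin(pmax(round(clip@samples * 32768), -32768), 32767)
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(as.integer(clip@rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip@rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")     # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(as.integer(x), con, size = 2, endian = "little")
  invisible(path)
}

#' Read a note label track
#'
#' Parses a tab-separated label track (Audacity label-track export
#' dialect): one `start<TAB>end<TAB>label` line per note, times in
#' seconds. Blank lines are skipped; segments are returned sorted by
#' start time.
#'
#' @param path path to the `.txt`/`.tsv` label file.
#' @return data.frame with columns `start`, `end` (numeric, seconds) and
#'   `label` (character).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("0.10\t0.25\ttrill\n0.30\t0.45\ttrill", f)
#' readLabelTrack(f)
#' @export
readLabelTrack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
      stop("line ", i, ": expected 3 tab-separated columns, got ",
           length(parts))
    start <- suppressWarnings(as.numeric(parts[1L]))
    end <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(start) || is.na(end))
      stop("line ", i, ": non-numeric start or end time")
    if (start >= end)
      stop("line ", i, ": start (", start, ") must be before end (", end, ")")
    out[[j]] <- data.frame(start = start, end = end, label = parts[3L],
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = numeric(), end = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a note label track
#'
#' Inverse of [readLabelTrack()]; times are written with six decimals so
#' that a write/read round trip preserves values to 1e-6 s.
#'
#' @param segments data.frame with columns `start`, `end`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabelTrack <- function(segments, path) {
  stopifnot(all(c("start", "end", "label") %in% names(segments)))
  writeLines(sprintf("%.6f\t%.6f\t%s", segments$start, segments$end,
                     segments$label), path)
  invisible(path)
}

#' Extract the audio of one note segment
#'
#' Sample-index convention is half-open with round-to-nearest endpoints:
#' the slice covers samples `[round(start*rate), round(end*rate))`, so
#' slicing a clip along any partition of its duration and concatenating
#' the pieces reproduces the original sample sequence exactly.
#'
#' @param clip an [AudioClip-class].
#' @param start,end note boundaries in seconds from clip start; `start`
#'   may instead be a one-row segment data.frame with columns
#'   `start`/`end` (as returned by [readLabelTrack()]).
#' @return An [AudioClip-class] with the note samples.
#' @export
sliceNote <- function(clip, start, end) {
  stopifnot(is(clip, "AudioClip"))
  if (is.data.frame(start)) {
    stopifnot(nrow(start) == 1L)
    end <- start$end
    start <- start$start
  }
  if (start >= end) stop("start must be before end")
  i0 <- round(start * clip@rate)
  i1 <- round(end * clip@rate)
  if (i0 < 0L || i1 > length(clip@samples))
    stop("segment [", start, ", ", end, ") lies outside the clip")
  AudioClip(clip@samples[(i0 + 1L):i1], clip@rate)
}

gcdInt <- function(a, b) if (b == 0) a else gcdInt(b, a %% b)

#' Resample a clip to an analysis rate
#'
#' All notes are brought to one common analysis rate before spectrogram
#' computation so that frequency and frame grids match across notes.
#' Uses polyphase resampling from the signal package for rational rate
#' ratios.
#'
#' @param clip an [AudioClip-class].
#' @param rate target rate in Hz.
#' @return An [AudioClip-class] at `rate`.
#' @export
resampleClip <- function(clip, rate) {
  stopifnot(is(clip, "AudioClip"))
  if (clip@rate == rate) return(clip)
  g <- gcdInt(as.integer(rate), as.integer(clip@rate))
  y <- signal::resample(clip@samples, rate / g, clip@rate / g)
  AudioClip(pmin(pmax(y, -1), 1), rate)
}
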