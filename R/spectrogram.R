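#' Short-time Fourier magnitude spectrogram
#'
#' Computes the linear-magnitude spectrogram used by the SPCC similarity
#' score: Hanning-windowed frames of `windowSamples` samples with
#' `overlapFraction` overlap between successive windows (hop =
#' `round(windowSamples * (1 - overlapFraction))` samples), magnitude of
#' the one-sided FFT (neither power nor dB).
#'
#' @param clip an [AudioClip-class] at the analysis rate.
#' @param windowSamples FFT window length in samples (default 512).
#' @param overlapFraction fractional overlap between successive windows
#'   (default 0.9).
#' @param windowShape window type; only `"hanning"` is provided.
#' @return A [SpectrogramMatrix-class]: `windowSamples/2 + 1` frequency
#'   bins by `floor((N - window)/hop) + 1` frames.
#' @examples
#' clip <- AudioClip(sin(2 * pi * 6000 * (0:4799) / 48000), 48000)
#' sg <- spectrogram(clip)
#' dim(sg@values)
#' @export
spectrogram <- function(clip, windowSamples = 512L, overlapFraction = 0.9,
                        windowShape = c("hanning")) {
  stopifnot(is(clip, "AudioClip"))
  windowShape <- match.arg(windowShape)
  x <- clip@samples
  n <- length(x)
  if (n < windowSamples)
    stop("clip shorter than one FFT window (", n, " < ", windowSamples,
         " samples); zero-pad at the caller if a spectrogram is required")
  hop <- max(1L, as.integer(round(windowSamples * (1 - overlapFraction))))
  nFrames <- (n - windowSamples) %/% hop + 1L
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(windowSamples - 1L)) / (windowSamples - 1L))
  idx <- outer(seq_len(windowSamples), (seq_len(nFrames) - 1L) * hop, "+")
  frames <- matrix(x[idx], nrow = windowSamples) * win
  spec <- Mod(stats::mvfft(frames))[seq_len(windowSamples %/% 2L + 1L), ,
                                    drop = FALSE]
  new("SpectrogramMatrix", values = spec,
      frameStep = hop / clip@rate, freqStep = clip@rate / windowSamples)
}

#' Zero-pad a clip to a minimum length
#'
#' Notes shorter than one FFT window are padded with trailing zeros so
#' they remain computable (and comparable) in the SPCC pipeline.
#'
#' @param clip an [AudioClip-class].
#' @param minSamples minimum length in samples.
#' @return An [AudioClip-class] of at least `minSamples` samples.
#' @export
padClip <- function(clip, minSamples) {
  stopifnot(is(clip, "AudioClip"))
  n <- length(clip@samples)
  if (n >= minSamples) return(clip)
  AudioClip(c(clip@samples, numeric(minSamples - n)), clip@rate)
}
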