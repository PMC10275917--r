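# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by brute force, separately from
# the package implementations they check.

# Brute-force SPCC: enumerate every candidate lag explicitly, compute the
# Pearson correlation over the overlap by the sum formulas.
bruteSpcc <- function(a, b, maxOffset = 0.020, offsetStep = 0.001,
                      minOverlap = 3L) {
  fs <- a@frameStep
  lags <- unique(as.integer(round(seq(-maxOffset, maxOffset,
                                      by = offsetStep) / fs)))
  na <- ncol(a@values); nb <- ncol(b@values)
  best <- -Inf
  for (k in lags) {
    cols <- list()
    for (i in seq_len(na)) {
      j <- i - k
      if (j >= 1L && j <= nb) cols[[length(cols) + 1L]] <- c(i, j)
    }
    if (length(cols) < minOverlap) next
    x <- c(); y <- c()
    for (cc in cols) {
      x <- c(x, a@values[, cc[1L]])
      y <- c(y, b@values[, cc[2L]])
    }
    nn <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- sum(x * y) - sx * sy / nn
    den <- sqrt((sum(x^2) - sx^2 / nn) * (sum(y^2) - sy^2 / nn))
    if (den == 0) next
    r <- num / den
    if (r > best) best <- r
  }
  if (!is.finite(best)) 0 else best
}

# Exhaustive signed-rank null: distribution of the positive-rank sum over
# all 2^n sign assignments (no zeros, no ties assumed).
enumSignedRank <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  pg <- mean(vs >= v)
  pl <- mean(vs <= v)
  p <- switch(alternative,
              greater = pg,
              less = pl,
              two.sided = if (v > n * (n + 1) / 4) min(1, 2 * pg)
                          else min(1, 2 * pl))
  list(V = v, p = p)
}

randomSpec <- function(bins, frames, frameStep = 0.001) {
  new("SpectrogramMatrix",
      values = matrix(abs(rnorm(bins * frames)), nrow = bins),
      frameStep = frameStep, freqStep = 100)
}

toneClip <- function(freq, durationS = 0.1, rate = 48000, amp = 0.8) {
  t <- (seq_len(round(durationS * rate)) - 1L) / rate
  AudioClip(amp * sin(2 * pi * freq * t), rate)
}

# Minimal song table for bout segmentation tests.
songTable <- function(types, starts, durations = 2, maleId = "m1") {
  data.frame(songId = sprintf("s%02d", seq_along(types)), maleId = maleId,
             start = starts, duration = durations, songType = types,
             stringsAsFactors = FALSE)
}

quietSongConfig <- function(...) {
  synthSongConfig(freqJitterSd = 0, durationJitterSd = 0, ampJitterSd = 0,
                  noiseLevel = 0, ...)
}

# Write a WAV file byte-by-byte, independent of the package writer, with
# arbitrary channel count and bit depth.
writeRawWav <- function(path, channels, rate, bits, intSamples) {
  con <- file(path, "wb")
  on.exit(close(con))
  bytesPerSample <- bits / 8
  dataSize <- length(intSamples) * bytesPerSample
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * channels * bytesPerSample), con, size = 4,
           endian = "little")
  writeBin(as.integer(channels * bytesPerSample), con, size = 2,
           endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(intSamples), con, size = 2, endian = "little")
  } else if (bits == 24) {
    v <- ifelse(intSamples < 0, intSamples + 16777216, intSamples)
    raw <- as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256))
    writeBin(raw, con)
  }
}
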