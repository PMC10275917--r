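test_that("spectrogram geometry and tone localization are correct", {
  clip <- toneClip(6000, 0.1, 48000)
  sg <- spectrogram(clip)
  hop <- 51L
  expect_equal(sg@frameStep, hop / 48000)
  expect_equal(sg@freqStep, 48000 / 512)
  expect_equal(ncol(sg@values), (48000 %/% 10 - 512L) %/% hop + 1L)
  expect_equal(nrow(sg@values), 257L)
  peakBin <- apply(sg@values, 2, which.max)
  expect_true(all(peakBin == round(6000 / sg@freqStep) + 1L))

  zeros <- AudioClip(numeric(2048), 48000)
  expect_true(all(spectrogram(zeros)@values == 0))

  expect_error(spectrogram(toneClip(1000, 0.005, 48000)),
               "shorter than one FFT window.*zero-pad")
})

test_that("chirp spectrogram tracks the known instantaneous frequency", {
  rate <- 48000
  t <- (0:(rate / 5 - 1)) / rate # 0.2 s
  k <- (8000 - 4000) / 0.2
  clip <- AudioClip(0.8 * sin(2 * pi * (4000 * t + k * t^2 / 2)), rate)
  sg <- spectrogram(clip)
  peakBin <- apply(sg@values, 2, which.max)
  expect_true(all(diff(peakBin) >= 0))
  # per-frame oracle: instantaneous frequency at each frame centre
  frames <- seq_len(ncol(sg@values))
  centre <- ((frames - 1L) * 51 + 256) / rate
  oracleBin <- round((4000 + k * centre) / sg@freqStep) + 1L
  expect_true(all(abs(peakBin - oracleBin) <= 2))
})

test_that("spccPair equals brute-force enumeration on random pairs", {
  set.seed(7)
  for (i in 1:20) {
    a <- randomSpec(3, sample(4:9, 1))
    b <- randomSpec(3, sample(4:9, 1))
    expect_equal(spccPair(a, b), bruteSpcc(a, b), tolerance = 1e-12)
  }
})

test_that("spccPair is symmetric, bounded, and 1 on self-comparison", {
  set.seed(8)
  for (i in 1:10) {
    a <- randomSpec(5, 8)
    b <- randomSpec(5, 8)
    expect_equal(spccPair(a, b), spccPair(b, a), tolerance = 1e-12)
    expect_gte(spccPair(a, b), -1)
    expect_lte(spccPair(a, b), 1)
    expect_equal(spccPair(a, a), 1)
  }
})

test_that("spccPair recovers shifts up to the maximum offset", {
  clip <- synthSong(quietSongConfig(), seed = 1)
  note <- sliceNote(clip@clip, trillNotes(clip)$start[1],
                    trillNotes(clip)$end[1])
  sg <- spectrogram(note)
  fs <- sg@frameStep
  maxFrames <- floor(0.020 / fs)
  for (k in c(1L, maxFrames %/% 2L, maxFrames)) {
    shifted <- new("SpectrogramMatrix",
                   values = cbind(matrix(0, nrow(sg@values), k),
                                  sg@values),
                   frameStep = fs, freqStep = sg@freqStep)
    expect_equal(spccPair(sg, shifted), 1, tolerance = 1e-9)
  }
})

test_that("silence against silence returns 0 with a warning, not NaN", {
  z <- new("SpectrogramMatrix", values = matrix(0, 4, 6),
           frameStep = 0.001, freqStep = 100)
  expect_warning(val <- spccPair(z, z), "zero-variance")
  expect_identical(val, 0)
})

test_that("note consistency is the off-diagonal row mean", {
  m2 <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(noteConsistency(m2, 1), 0.8)
  expect_equal(noteConsistency(m2, 2), 0.8)
  m3 <- diag(3)
  m3[1, 2] <- m3[2, 1] <- 0.9
  m3[1, 3] <- m3[3, 1] <- 0.7
  m3[2, 3] <- m3[3, 2] <- 0.5
  expect_equal(noteConsistency(m3, 1), 0.8)
  expect_error(noteConsistency(matrix(1, 1, 1), 1), "fewer than 2")
})

test_that("song consistency equals the unordered-pair mean", {
  song <- synthSong(synthSongConfig(freqJitterSd = 150), seed = 3)
  res <- songConsistencyFromSong(song)
  m <- pairMatrix(res)
  expect_equal(songScore(res), mean(m[upper.tri(m)]), tolerance = 1e-12)
  expect_equal(noteScores(res),
               vapply(seq_len(nrow(m)), function(i) mean(m[i, -i]),
                      numeric(1)))
  expect_error(songConsistency(list(toneClip(4000))), "fewer than 2")
})

test_that("identical notes give song consistency exactly 1", {
  note <- toneClip(4000, 0.05, 48000)
  res <- songConsistency(list(note, note, note, note))
  expect_equal(songScore(res), 1, tolerance = 1e-12)
  expect_true(all(noteScores(res) == 1))
})

test_that("frequency jitter degrades consistency in nearly all replicates", {
  wins <- 0L
  nRep <- 60L
  for (i in seq_len(nRep)) {
    s0 <- synthSong(synthSongConfig(freqJitterSd = 0, nTrill = 4),
                    seed = 1000L + i)
    s200 <- synthSong(synthSongConfig(freqJitterSd = 200, nTrill = 4),
                      seed = 1000L + i)
    if (songScore(songConsistencyFromSong(s0)) >
        songScore(songConsistencyFromSong(s200))) wins <- wins + 1L
  }
  expect_gte(wins / nRep, 0.95)
})

test_that("mean consistency degrades monotonically with each jitter source", {
  meanScore <- function(cfg, seeds) {
    mean(vapply(seeds, function(s)
      songScore(songConsistencyFromSong(synthSong(cfg, seed = s))),
      numeric(1)))
  }
  seeds <- 1:40
  base <- list(nTrill = 4L, noteDuration = 0.04)

  freqLevels <- c(0, 100, 250)
  mFreq <- vapply(freqLevels, function(j)
    meanScore(do.call(synthSongConfig, c(base, list(freqJitterSd = j))),
              seeds), numeric(1))
  expect_true(all(diff(mFreq) <= 0))

  durLevels <- c(0, 0.012)
  mDur <- vapply(durLevels, function(j)
    meanScore(do.call(synthSongConfig,
                      c(base, list(freqJitterSd = 0, durationJitterSd = j))),
              seeds), numeric(1))
  expect_true(all(diff(mDur) <= 0))

  noiseLevels <- c(0.01, 0.8)
  mNoise <- vapply(noiseLevels, function(j)
    meanScore(do.call(synthSongConfig,
                      c(base, list(freqJitterSd = 0, noiseLevel = j))),
              seeds), numeric(1))
  expect_true(all(diff(mNoise) <= 0))
})
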