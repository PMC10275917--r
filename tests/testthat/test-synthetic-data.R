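test_that("synthetic songs are deterministic given a seed", {
  cfg <- synthSongConfig()
  s1 <- synthSong(cfg, seed = 10)
  s2 <- synthSong(cfg, seed = 10)
  expect_identical(samples(s1@clip), samples(s2@clip))
  expect_identical(notes(s1), notes(s2))
  s3 <- synthSong(cfg, seed = 11)
  expect_false(identical(samples(s1@clip), samples(s3@clip)))
})

test_that("song structure, annotation alignment and duration floor hold", {
  cfg <- synthSongConfig(nIntro = 2, nTrill = 5)
  song <- synthSong(cfg, seed = 1)
  expect_equal(nrow(notes(song)), 7L)
  expect_equal(trillIndex(song), 3L)
  expect_equal(notes(song)$label, c(rep("intro", 2), rep("trill", 5)))
  # annotations align with the rendered audio to the sample
  for (i in seq_len(nrow(notes(song)))) {
    seg <- notes(song)[i, ]
    piece <- sliceNote(song@clip, seg$start, seg$end)
    expect_equal(length(samples(piece)),
                 round((seg$end - seg$start) * sampleRate(song@clip)))
    expect_gt(max(abs(samples(piece))), 0)
  }

  # zero-jitter trill notes with constant frequency share one peak bin
  quiet <- synthSong(quietSongConfig(), seed = 2)
  tn <- trillNotes(quiet)
  bins <- vapply(seq_len(nrow(tn)), function(i) {
    sg <- spectrogram(padClip(sliceNote(quiet@clip, tn$start[i], tn$end[i]),
                              512L))
    which.max(rowSums(sg@values))
  }, integer(1))
  expect_length(unique(bins), 1L)

  # extreme duration jitter is clamped at 25% of nominal
  wild <- synthSongConfig(durationJitterSd = 1)
  durs <- replicate(30, {
    s <- synthSong(wild, seed = sample.int(1e6, 1))
    n <- trillNotes(s)
    min(n$end - n$start)
  })
  expect_true(all(durs >= 0.25 * wild$noteDuration - 1e-9))
})

test_that("zero-jitter songs measure vocal consistency 1", {
  song <- synthSong(quietSongConfig(), seed = 5)
  expect_equal(songScore(songConsistencyFromSong(song)), 1,
               tolerance = 1e-6)
})

test_that("dawn sessions carry recoverable ground-truth bout structure", {
  types <- list(A = quietSongConfig(f0 = 3800),
                B = quietSongConfig(f0 = 4600))
  ses <- synthDawnSession(types, boutTypes = c("A", "A", "B"),
                          boutLengths = c(10L, 8L, 12L),
                          pauseBetweenBouts = 90, seed = 3)
  expect_equal(ses$groundTruth$precededBy,
               c("session_start", "silence_gap", "type_switch"))
  bouts <- segmentBouts(ses$songTable)
  expect_length(bouts, 3L)
  expect_equal(vapply(bouts, function(b) nrow(boutSongs(b)), integer(1)),
               ses$groundTruth$nSongs)
  expect_equal(vapply(bouts, precededBy, character(1)),
               ses$groundTruth$precededBy)
  expect_equal(vapply(bouts, songType, character(1)),
               ses$groundTruth$songType)

  expect_error(synthDawnSession(types, "A", 3L, pauseBetweenBouts = 30),
               "exceed 60")
})

test_that("random sessions are always segmented back exactly", {
  types <- list(A = quietSongConfig(nTrill = 3, noteDuration = 0.03),
                B = quietSongConfig(nTrill = 3, noteDuration = 0.03,
                                    f0 = 5000))
  for (seed in 31:33) {
    nb <- withr::with_seed(seed, sample(2:4, 1))
    bt <- withr::with_seed(seed + 1, sample(c("A", "B"), nb, replace = TRUE))
    bl <- withr::with_seed(seed + 2, sample(3:6, nb, replace = TRUE))
    ses <- synthDawnSession(types, bt, bl, seed = seed)
    bouts <- segmentBouts(ses$songTable)
    expect_equal(vapply(bouts, songType, character(1)),
                 ses$groundTruth$songType)
    expect_equal(vapply(bouts, precededBy, character(1)),
                 ses$groundTruth$precededBy)
  }
})

test_that("simulated responses follow the logistic process", {
  # fair coin when every coefficient is zero
  flat <- simulateResponses(intercept = 0, betaSwitch = 0, betaLogPos = 0,
                            betaInteraction = 0, femaleSd = 0,
                            nFemales = 50, boutsPerFemale = 10,
                            positionsPerBout = 20, seed = 8)
  rate <- mean(flat$response)
  se <- sqrt(0.25 / nrow(flat))
  expect_lt(abs(rate - 0.5), 2.5 * se)

  # habituation: response at position 1 exceeds position 15
  hab <- simulateResponses(nFemales = 200, seed = 9)
  sil <- hab[hab$precededBy == "silence_gap", ]
  expect_gt(mean(sil$response[sil$position == 1]),
            mean(sil$response[sil$position == 15]))

  # reproducibility
  expect_identical(simulateResponses(nFemales = 5, seed = 1),
                   simulateResponses(nFemales = 5, seed = 1))
})

test_that("numeric warm-up generator matches its declared process", {
  d <- simulateWarmup(seed = 99)
  expect_equal(nrow(d), 18 * 4 * 15)
  expect_true(all(d$stdConsistency[d$position == 1] == 0))
  # injected slope appears in the standardized series means
  fit <- lm(stdConsistency ~ position, data = d)
  expect_equal(unname(coef(fit)["position"]), 0.002, tolerance = 0.004)
})

test_that("calibrated declining jitter yields a positive warm-up trend", {
  cfg <- synthSongConfig(nTrill = 4, noteDuration = 0.04,
                         freqJitterSd = 250)
  types <- list(A = cfg)
  series <- list()
  for (m in 1:2) {
    ses <- synthDawnSession(types, boutTypes = rep("A", 3),
                            boutLengths = rep(8L, 3),
                            warmupSlope = 0.015, seed = 40 + m,
                            maleId = paste0("m", m))
    cons <- vapply(ses$songs, function(s)
      songScore(songConsistencyFromSong(s)), numeric(1))
    names(cons) <- names(ses$songs)
    for (b in segmentBouts(ses$songTable))
      series[[length(series) + 1L]] <- warmupSeries(b, cons)
  }
  fit <- warmupTrend(do.call(rbind, series))
  expect_gt(fit$estimate, 0)
})
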