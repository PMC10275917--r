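test_that("label tracks parse, skip blanks and report malformed lines", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.10\t0.25\ttrill", "", "0.30\t0.45\ttrill"), f)
  seg <- readLabelTrack(f)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$end - seg$start, c(0.15, 0.15))
  expect_equal(seg$label, c("trill", "trill"))

  writeLines(character(), f)
  expect_equal(nrow(readLabelTrack(f)), 0L)

  writeLines("0.5\t0.2\tx", f)
  expect_error(readLabelTrack(f), "line 1.*start")

  writeLines(c("0.1\t0.2\ta", "0.3\tb"), f)
  expect_error(readLabelTrack(f), "line 2.*3 tab-separated")

  writeLines("abc\t0.2\ta", f)
  expect_error(readLabelTrack(f), "line 1.*non-numeric")
})

test_that("label tracks are sorted on read and round-trip to 1e-6", {
  f <- withr::local_tempfile(fileext = ".txt")
  seg <- data.frame(start = c(0.531, 0.123456, 0.30001),
                    end = c(0.6, 0.2, 0.4), label = c("c", "a", "b"))
  writeLabelTrack(seg, f)
  back <- readLabelTrack(f)
  expect_equal(back$label, c("a", "b", "c"))
  expect_equal(back$start, sort(seg$start), tolerance = 1e-6)
  expect_equal(back$end, sort(seg$end), tolerance = 1e-6)
})

test_that("WAV reading applies integer scaling and averages channels", {
  f <- withr::local_tempfile(fileext = ".wav")
  # 16-bit full-scale square wave: +32767 maps to 32767/32768, -32768 to -1
  writeRawWav(f, channels = 1, rate = 48000, bits = 16,
              intSamples = rep(c(32767L, -32768L), 100))
  clip <- readWav(f)
  expect_equal(sampleRate(clip), 48000)
  expect_equal(unique(samples(clip)), c(32767 / 32768, -1))

  # stereo with channels x and -x averages to silence
  x <- as.integer(round(16000 * sin(2 * pi * 440 * (0:199) / 8000)))
  writeRawWav(f, channels = 2, rate = 8000, bits = 16,
              intSamples = as.vector(rbind(x, -x)))
  expect_true(all(samples(readWav(f)) == 0))

  # 24-bit scaling: full-scale values map to (2^23-1)/2^23 and -1
  writeRawWav(f, channels = 1, rate = 48000, bits = 24,
              intSamples = c(8388607L, -8388608L, 4194304L))
  expect_equal(samples(readWav(f)),
               c(8388607 / 8388608, -1, 0.5))
})

test_that("WAV write/read round-trips within 16-bit quantization", {
  f <- withr::local_tempfile(fileext = ".wav")
  clip <- toneClip(440, 0.05, 8000)
  writeWav(clip, f)
  back <- readWav(f)
  expect_equal(sampleRate(back), 8000)
  expect_equal(length(samples(back)), length(samples(clip)))
  expect_lt(max(abs(samples(back) - samples(clip))), 1 / 32768)

  expect_error(readWav(withr::local_tempfile()), "no such file")
})

test_that("sliceNote uses half-open rounded sample windows", {
  clip <- AudioClip(rnorm(48000), 48000)
  expect_equal(samples(sliceNote(clip, 0, 1)), samples(clip))
  expect_equal(length(samples(sliceNote(clip, 0.10, 0.25))), 7200L)
  expect_error(sliceNote(clip, 0.9, 1.1), "outside")
  expect_error(sliceNote(clip, 0.5, 0.5), "before end")
  # segment data.frame form
  seg <- data.frame(start = 0.1, end = 0.2, label = "n")
  expect_equal(length(samples(sliceNote(clip, seg))), 4800L)
})

test_that("slicing along any partition reproduces the clip exactly", {
  set.seed(42)
  clip <- AudioClip(rnorm(12000), 8000)
  for (rep in 1:5) {
    cuts <- sort(runif(sample(1:6, 1), 0, duration(clip)))
    bounds <- unique(c(0, cuts, duration(clip)))
    pieces <- lapply(seq_len(length(bounds) - 1L), function(i)
      samples(sliceNote(clip, bounds[i], bounds[i + 1L])))
    expect_identical(unlist(pieces), samples(clip))
  }
})

test_that("assembleSongs sets the trill index and flags short trills", {
  cfgClip <- toneClip(1000, 0.1, 8000)
  labels <- data.frame(start = c(0.01, 0.03, 0.05, 0.07, 0.09) / 1,
                       end = c(0.02, 0.04, 0.06, 0.08, 0.098),
                       label = c("intro", "intro", "trill", "trill", "trill"))
  md <- data.frame(song_id = c("s1", "s2"), male_id = "m1",
                   timestamp = "2020-04-20T05:00:00", context = "dawn",
                   song_type = "A")
  out <- assembleSongs(list(s1 = cfgClip), list(s1 = labels), md)
  expect_equal(trillIndex(out$songs$s1), 3L)
  expect_true(out$consistencyEligible[["s1"]])
  expect_equal(nrow(trillNotes(out$songs$s1)), 3L)

  # a single-note trill is kept but flagged ineligible
  lab1 <- labels[1:3, ]
  expect_warning(
    out1 <- assembleSongs(list(s1 = cfgClip), list(s1 = lab1), md),
    "excluded from consistency")
  expect_false(out1$consistencyEligible[["s1"]])

  expect_error(
    assembleSongs(list(sX = cfgClip), list(sX = labels), md),
    "no metadata.*sX")
  expect_error(
    assembleSongs(list(s1 = cfgClip), list(s2 = labels), md),
    "no label track.*s1")
})
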