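test_that("bout segmentation splits on type switches and long pauses", {
  tab <- songTable(c("A", "A", "A", "B", "B", "B"),
                   starts = seq(0, 50, by = 10))
  bouts <- segmentBouts(tab)
  expect_length(bouts, 2L)
  expect_equal(precededBy(bouts[[1]]), "session_start")
  expect_equal(precededBy(bouts[[2]]), "type_switch")
  expect_equal(songType(bouts[[2]]), "B")
  expect_false(any(vapply(bouts, isSubMinimal, logical(1))))

  # 90 s silent gap splits even without a type switch
  tab2 <- songTable(rep("A", 6), starts = c(0, 10, 20, 112, 122, 132))
  bouts2 <- segmentBouts(tab2)
  expect_length(bouts2, 2L)
  expect_equal(precededBy(bouts2[[2]]), "silence_gap")
  expect_equal(songType(bouts2[[2]]), "A")

  # a gap of exactly 60 s does not split (rule is "longer than 1 min")
  tab3 <- songTable(rep("A", 4), starts = c(0, 10, 72, 82))
  expect_length(segmentBouts(tab3), 1L)

  expect_error(segmentBouts(songTable(c("A", "A"), c(10, 0))), "ordered")
})

test_that("runs shorter than three songs are flagged sub-minimal", {
  tab <- songTable(c("A", "A", "B", "B", "B"), starts = seq(0, 40, 10))
  bouts <- segmentBouts(tab)
  expect_length(bouts, 2L)
  expect_true(isSubMinimal(bouts[[1]]))
  expect_false(isSubMinimal(bouts[[2]]))
  expect_equal(nrow(boutSongs(bouts[[2]])), 3L)
})

test_that("bout segmentation partitions the input songs", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    types <- sample(c("A", "B", "C"), n, replace = TRUE)
    gaps <- sample(c(5, 15, 100), n - 1, replace = TRUE,
                   prob = c(0.6, 0.3, 0.1))
    starts <- cumsum(c(0, gaps + 2))
    tab <- songTable(types, starts, durations = 2)
    bouts <- segmentBouts(tab)
    ids <- unlist(lapply(bouts, function(b) boutSongs(b)$songId))
    expect_identical(sort(ids), sort(tab$songId))
    expect_false(any(duplicated(ids)))
    # within every bout: one type, no silent pause above threshold
    for (b in bouts) {
      s <- boutSongs(b)
      expect_length(unique(s$songType), 1L)
      if (nrow(s) > 1L)
        expect_true(all(s$start[-1L] -
                          (s$start[-nrow(s)] + s$duration[-nrow(s)]) <= 60))
    }
  }
})

test_that("warm-up series standardize to a zero first position", {
  tab <- songTable(rep("A", 3), starts = c(0, 5, 10))
  tab$consistency <- c(0.80, 0.82, 0.85)
  b <- segmentBouts(tab)[[1]]
  ws <- warmupSeries(b)
  expect_equal(ws$stdConsistency, c(0, 0.02, 0.05))
  expect_equal(ws$position, 1:3)

  # constant consistency gives all zeros
  tab$consistency <- 0.8
  expect_true(all(warmupSeries(segmentBouts(tab)[[1]])$stdConsistency == 0))

  # 20-song bouts are truncated at 15 positions
  tab20 <- songTable(rep("A", 20), starts = seq(0, 95, 5))
  tab20$consistency <- runif(20, 0.7, 0.9)
  expect_equal(max(warmupSeries(segmentBouts(tab20)[[1]])$position), 15L)

  # missing baseline: skipped with a warning
  tab$consistency <- c(NA, 0.82, 0.85)
  expect_warning(out <- warmupSeries(segmentBouts(tab)[[1]]),
                 "baseline undefined")
  expect_null(out)

  # interior missing values are dropped, positions preserved
  tab$consistency <- c(0.8, NA, 0.85)
  ws2 <- warmupSeries(segmentBouts(tab)[[1]])
  expect_equal(ws2$position, c(1L, 3L))
})

test_that("warm-up trend recovers a noiseless slope exactly", {
  ser <- do.call(rbind, lapply(1:4, function(b)
    data.frame(boutId = paste0("b", b), maleId = "m1", position = 1:10,
               stdConsistency = 0.01 * (1:10 - 1))))
  expect_warning(fit <- warmupTrend(ser), "single individual")
  expect_equal(fit$estimate, 0.01, tolerance = 1e-10)
  expect_equal(fit$method, "ols")
})

test_that("warm-up trend CI covers zero under a null simulation", {
  covers <- 0L
  nRep <- 20L
  for (i in seq_len(nRep)) {
    d <- simulateWarmup(slope = 0, nIndividuals = 10, seed = 200L + i)
    fit <- warmupTrend(d[, c("boutId", "maleId", "position",
                             "stdConsistency")])
    if (fit$ci[1] <= 0 && 0 <= fit$ci[2]) covers <- covers + 1L
  }
  expect_gte(covers / nRep, 0.8)
})

test_that("song rate and repertoire size follow their definitions", {
  expect_equal(songRate(10, 120), 5)
  expect_equal(songRate(0, 60), 0)
  expect_equal(songRate(1, 12), 5)
  expect_error(songRate(1, 0), "positive")

  expect_equal(repertoireSize(c("A", "A", "B")), 2L)
  expect_equal(repertoireSize(character()), 0L)
  expect_equal(repertoireSize(LETTERS[1:7]), 7L)
})

test_that("seasonal table bins weeks by floor and centres per male", {
  firstEgg <- c(m1 = as.Date("2020-04-22"))
  tab <- data.frame(maleId = "m1",
                    date = as.Date("2020-04-22") + c(-10, 0, 3),
                    context = "dawn", consistency = c(0.7, 0.9, 0.8))
  out <- seasonalTable(tab, firstEgg)
  expect_equal(out$weeksToFirstEgg, c(-2L, 0L, 0L))
  expect_equal(mean(out$normConsistency), 0)
  expect_equal(out$normConsistency, c(-0.1, 0.1, 0))

  tab2 <- rbind(tab, data.frame(maleId = "m2", date = as.Date("2020-04-25"),
                                context = "dawn", consistency = 0.75))
  expect_warning(out2 <- seasonalTable(tab2, firstEgg), "m2")
  expect_false("m2" %in% out2$maleId)
})
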