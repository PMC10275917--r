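songTableFromSongs <- function(songs) {
  stopifnot(length(songs) > 0L)
  do.call(rbind, lapply(songs, function(s) {
    stopifnot(is(s, "AnnotatedSong"))
    dur <- if (!is.null(s@clip)) duration(s@clip)
           else if (nrow(s@notes)) max(s@notes$end) else 0
    data.frame(songId = s@songId, maleId = s@maleId,
               start = as.numeric(s@timestamp), duration = dur,
               songType = s@songType, stringsAsFactors = FALSE)
  }))
}

#' Segment a singing session into song-type bouts
#'
#' A song-type bout is a string of continuous song in which the same
#' song type is repeated at least three times before the male stops or
#' switches type. A new bout starts at the session start, at any change
#' of song type, or after a silent pause longer than `pauseThreshold`
#' seconds — even without a type switch. The pause is measured from the
#' end of one song to the start of the next. Runs of fewer than three
#' songs are emitted flagged sub-minimal (excluded from warm-up
#' analysis) so that every input song appears in exactly one bout.
#'
#' @param songs either a list of [AnnotatedSong-class] from one male and
#'   session ordered by timestamp, or a data.frame with columns
#'   `songId`, `maleId`, `start` (seconds), `duration` (seconds),
#'   `songType` (and optionally `consistency`).
#' @param pauseThreshold silent-pause threshold in seconds (default 60,
#'   i.e. the 1-minute rule).
#' @return list of [SongTypeBout-class] in temporal order.
#' @examples
#' tab <- data.frame(songId = paste0("s", 1:6), maleId = "m1",
#'                   start = c(0, 10, 20, 30, 40, 50), duration = 2,
#'                   songType = c("A", "A", "A", "B", "B", "B"))
#' segmentBouts(tab)
#' @export
segmentBouts <- function(songs, pauseThreshold = 60) {
  tab <- if (is.data.frame(songs)) songs else songTableFromSongs(songs)
  need <- c("songId", "maleId", "start", "duration", "songType")
  stopifnot(all(need %in% names(tab)))
  if (nrow(tab) == 0L) return(list())
  if (is.unsorted(tab$start))
    stop("songs must be ordered by start time")
  if (length(unique(tab$maleId)) > 1L)
    stop("segmentBouts expects songs from a single male session")

  n <- nrow(tab)
  gapBefore <- c(NA_real_,
                 tab$start[-1L] - (tab$start[-n] + tab$duration[-n]))
  newBout <- rep(FALSE, n)
  newBout[1L] <- TRUE
  if (n > 1L) {
    typeChange <- tab$songType[-1L] != tab$songType[-n]
    longPause <- gapBefore[-1L] > pauseThreshold
    newBout[-1L] <- typeChange | longPause
  }
  boutNo <- cumsum(newBout)
  out <- vector("list", max(boutNo))
  for (b in seq_len(max(boutNo))) {
    rows <- which(boutNo == b)
    first <- rows[1L]
    preceded <- if (first == 1L) "session_start"
                else if (gapBefore[first] > pauseThreshold) "silence_gap"
                else "type_switch"
    songsDf <- tab[rows, , drop = FALSE]
    songsDf$position <- seq_along(rows)
    rownames(songsDf) <- NULL
    out[[b]] <- new("SongTypeBout",
      boutId = sprintf("%s_b%02d", tab$maleId[1L], b),
      maleId = tab$maleId[1L], songType = tab$songType[first],
      songs = songsDf, precededBy = preceded,
      subMinimal = length(rows) < 3L)
  }
  out
}

#' Within-bout warm-up series of standardized consistency
#'
#' Selects the first `maxPositions` repetitions of the song type in a
#' bout and standardizes vocal consistency within the bout by
#' subtracting the consistency of the first song, so position 1 is
#' exactly 0 and later values measure the within-bout change. Songs with
#' missing consistency (e.g. overlapped by extraneous sound) are dropped
#' while their positions are preserved; if the first song is missing the
#' bout is skipped with a warning because the baseline is undefined.
#'
#' @param bout a [SongTypeBout-class].
#' @param consistencyBySong named numeric vector of per-song vocal
#'   consistency keyed by `songId`; omit if the bout's song table already
#'   has a `consistency` column.
#' @param maxPositions number of leading repetitions analysed
#'   (default 15).
#' @return data.frame with columns `boutId`, `maleId`, `position`,
#'   `stdConsistency`, or `NULL` when the baseline is missing or the
#'   bout is sub-minimal.
#' @export
warmupSeries <- function(bout, consistencyBySong = NULL, maxPositions = 15L) {
  stopifnot(is(bout, "SongTypeBout"))
  if (bout@subMinimal) return(NULL)
  tab <- bout@songs
  cons <- if (is.null(consistencyBySong)) {
    if (!"consistency" %in% names(tab))
      stop("no consistency column and no consistencyBySong given")
    tab$consistency
  } else {
    unname(consistencyBySong[tab$songId])
  }
  keep <- tab$position <= maxPositions
  pos <- tab$position[keep]
  cons <- cons[keep]
  if (!length(pos) || pos[1L] != 1L || is.na(cons[1L])) {
    warning("bout ", bout@boutId,
            " skipped: first-song consistency missing, baseline undefined")
    return(NULL)
  }
  ok <- !is.na(cons)
  data.frame(boutId = bout@boutId, maleId = bout@maleId,
             position = pos[ok], stdConsistency = cons[ok] - cons[1L],
             stringsAsFactors = FALSE)
}

#' Mixed-model estimate of the within-bout warm-up trend
#'
#' Fits the within-bout change in standardized vocal consistency as a
#' linear function of repetition number with a random intercept per
#' individual, and returns the slope (consistency units per repetition)
#' with its Wald 95% CI and the variance components. With a single
#' individual the grouping term is degenerate, and the function falls
#' back to ordinary least squares with a warning.
#'
#' @param series a data.frame as produced by row-binding
#'   [warmupSeries()] outputs (columns `boutId`, `maleId`, `position`,
#'   `stdConsistency`), or a list of such frames.
#' @return list with `estimate` (slope), `se`, `ci` (length-2), `tValue`,
#'   `intercept`, `individualSD`, `residualSD`, `nObs`, `nIndividuals`,
#'   `method` and the fitted `model`.
#' @export
warmupTrend <- function(series) {
  if (is.list(series) && !is.data.frame(series))
    series <- do.call(rbind, Filter(Negate(is.null), series))
  stopifnot(is.data.frame(series), nrow(series) > 2L)
  if (length(unique(series$boutId)) < 2L)
    stop("warm-up trend needs at least 2 bouts")
  nInd <- length(unique(series$maleId))
  if (nInd < 2L) {
    warning("single individual: falling back to ordinary least squares")
    fit <- stats::lm(stdConsistency ~ position, data = series)
    co <- summary(fit)$coefficients
    est <- co["position", "Estimate"]
    se <- co["position", "Std. Error"]
    return(list(estimate = est, se = se,
                ci = est + c(-1, 1) * stats::qnorm(0.975) * se,
                tValue = co["position", "t value"],
                intercept = co["(Intercept)", "Estimate"],
                individualSD = NA_real_, residualSD = summary(fit)$sigma,
                nObs = nrow(series), nIndividuals = nInd,
                method = "ols", model = fit))
  }
  fit <- lme4::lmer(stdConsistency ~ position + (1 | maleId), data = series,
                    REML = TRUE)
  co <- as.data.frame(summary(fit)$coefficients)
  est <- co["position", "Estimate"]
  se <- co["position", "Std. Error"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(estimate = est, se = se,
       ci = est + c(-1, 1) * stats::qnorm(0.975) * se,
       tValue = co["position", "t value"],
       intercept = co["(Intercept)", "Estimate"],
       individualSD = vc$sdcor[vc$grp == "maleId"],
       residualSD = vc$sdcor[vc$grp == "Residual"],
       nObs = nrow(series), nIndividuals = nInd,
       method = "lmm", model = fit)
}

#' Song rate
#'
#' Number of songs per minute in an observation window.
#'
#' @param nSongs number of songs observed.
#' @param windowSeconds window length in seconds (> 0).
#' @return Songs per minute.
#' @examples
#' songRate(10, 120) # 5 songs per minute
#' @export
songRate <- function(nSongs, windowSeconds) {
  if (windowSeconds <= 0) stop("window must be positive")
  nSongs / windowSeconds * 60
}

#' Repertoire size
#'
#' Number of distinct song types in a male's recorded songs.
#'
#' @param songTypes character vector of song-type labels (or a list of
#'   [AnnotatedSong-class]).
#' @return Integer count of distinct types.
#' @export
repertoireSize <- function(songTypes) {
  if (is.list(songTypes) && length(songTypes) &&
      is(songTypes[[1L]], "AnnotatedSong"))
    songTypes <- vapply(songTypes, songType, character(1))
  length(unique(songTypes[!is.na(songTypes)]))
}

#' Seasonal table of within-individual normalized consistency
#'
#' Bins each song into whole weeks relative to the male's first-egg date
#' (`floor(days/7)`, so the first-egg date itself falls in week 0) and
#' normalizes vocal consistency within individual by subtracting the
#' male's mean, so values above zero mean consistency was above that
#' male's average. Smoothing over the season is left to downstream
#' modelling.
#'
#' @param songTable data.frame with columns `maleId`, `date`
#'   (Date/POSIXct), `context`, `consistency`.
#' @param firstEggDates named vector of first-egg dates (Date), keyed by
#'   male id; males without a date are excluded with a warning.
#' @return data.frame with `maleId`, `weeksToFirstEgg`, `context`,
#'   `normConsistency`.
#' @export
seasonalTable <- function(songTable, firstEggDates) {
  need <- c("maleId", "date", "context", "consistency")
  stopifnot(all(need %in% names(songTable)))
  known <- songTable$maleId %in% names(firstEggDates)
  if (any(!known)) {
    warning("excluding male(s) without first-egg date: ",
            paste(unique(songTable$maleId[!known]), collapse = ", "))
    songTable <- songTable[known, , drop = FALSE]
  }
  if (!nrow(songTable))
    return(data.frame(maleId = character(), weeksToFirstEgg = integer(),
                      context = character(), normConsistency = numeric()))
  days <- as.numeric(as.Date(songTable$date) -
                       as.Date(firstEggDates[songTable$maleId]))
  weeks <- as.integer(floor(days / 7))
  norm <- songTable$consistency -
    stats::ave(songTable$consistency, songTable$maleId)
  data.frame(maleId = songTable$maleId, weeksToFirstEgg = weeks,
             context = songTable$context, normConsistency = norm,
             stringsAsFactors = FALSE)
}
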