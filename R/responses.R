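solicitationClasses <- c("copulation", "twittering", "chattering")

#' Score female vocal responses against a playback cue table
#'
#' Turns a log of classified female calls into the binary per-song and
#' per-bout response variables of the playback analysis. Only calls
#' associated with copulation solicitation displays (classes
#' `copulation`, `twittering`, `chattering`) count as response; churring,
#' screaming and unclassified calls are ignored. A song position scores
#' 1 if at least one solicitation-class call falls inside that song's
#' window (from its onset to the next onset, or to the bout end for the
#' last song). Bouts played entirely while the female was outside the
#' nest box are removed.
#'
#' @param callEvents data.frame with columns `time` (seconds from trial
#'   start) and `callClass`.
#' @param cues cue table from [renderSchedule()].
#' @param occupancy data.frame of in-box intervals with columns `start`,
#'   `end` (seconds), or `NULL` if the female was present throughout.
#' @param trialId,femaleId identifiers stamped onto the output.
#' @return data.frame, one row per song position, with columns
#'   `trialId`, `femaleId`, `boutIndex`, `songType`, `precededBy`,
#'   `position`, `response` (0/1), `inBox` (fraction of the bout the
#'   female was inside).
#' @seealso [boutResponses()] for the per-bout summary.
#' @export
scoreResponses <- function(callEvents, cues, occupancy = NULL,
                           trialId = "trial1", femaleId = "f1") {
  stopifnot(all(c("time", "callClass") %in% names(callEvents)))
  trialEnd <- max(cues$boutEnd)
  outside <- callEvents$time < 0 | callEvents$time > trialEnd
  if (any(outside)) {
    warning(sum(outside), " call(s) outside the trial window ignored")
    callEvents <- callEvents[!outside, , drop = FALSE]
  }
  sol <- callEvents$time[callEvents$callClass %in% solicitationClasses]

  overlapFraction <- function(a, b) {
    if (is.null(occupancy)) return(1)
    ov <- pmin(occupancy$end, b) - pmax(occupancy$start, a)
    sum(pmax(ov, 0)) / (b - a)
  }

  out <- lapply(split(cues, cues$boutIndex), function(bc) {
    bc <- bc[order(bc$position), , drop = FALSE]
    windowEnd <- c(bc$time[-1L], bc$boutEnd[1L])
    resp <- vapply(seq_len(nrow(bc)), function(i)
      as.integer(any(sol >= bc$time[i] & sol < windowEnd[i])), integer(1))
    data.frame(trialId = trialId, femaleId = femaleId,
               boutIndex = bc$boutIndex[1L], songType = bc$songType[1L],
               precededBy = bc$precededBy[1L], position = bc$position,
               response = resp,
               inBox = overlapFraction(bc$boutStart[1L], bc$boutEnd[1L]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  absent <- res$inBox == 0
  if (any(absent))
    res <- res[!absent, , drop = FALSE]
  res
}

#' Per-bout summary of a position-level response table
#'
#' Collapses the per-song response table from [scoreResponses()] to one
#' row per song-type bout with the binomial yes/no response (1 if the
#' female vocalized at least once during the bout).
#'
#' @param responses data.frame from [scoreResponses()].
#' @return data.frame with one row per bout: `trialId`, `femaleId`,
#'   `boutIndex`, `songType`, `precededBy`, `nPositions`, `anyResponse`,
#'   `inBox`.
#' @export
boutResponses <- function(responses) {
  out <- lapply(split(responses, responses[c("trialId", "boutIndex")],
                      drop = TRUE), function(d) {
    data.frame(trialId = d$trialId[1L], femaleId = d$femaleId[1L],
               boutIndex = d$boutIndex[1L], songType = d$songType[1L],
               precededBy = d$precededBy[1L], nPositions = nrow(d),
               anyResponse = as.integer(any(d$response == 1L)),
               inBox = d$inBox[1L], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$trialId, res$boutIndex), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Paired comparison of response between Song and Silence treatments
#'
#' Wilcoxon signed-rank test on paired per-female response proportions
#' under the Song and the Silence treatment. Zero differences are
#' dropped; the exact null distribution is used for up to 25 nonzero
#' pairs without ties, the normal approximation otherwise. The
#' Hodges-Lehmann confidence interval on the median difference is
#' reported.
#'
#' @param song,silence equal-length numeric vectors of per-female
#'   response proportions under the two treatments.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   for the alternative on `song - silence`.
#' @param conf.level confidence level for the CI (default 0.95).
#' @return list with `V` (rank sum of positive `song - silence`
#'   differences), `VLesser` (rank sum of the lesser-rank side), `p`,
#'   `ci`, `medianDifference` (Hodges-Lehmann), `nPairs` (nonzero),
#'   `exact`.
#' @export
treatmentComparison <- function(song, silence,
                                alternative = c("two.sided", "greater",
                                                "less"),
                                conf.level = 0.95) {
  alternative <- match.arg(alternative)
  stopifnot(length(song) == length(silence))
  d <- song - silence
  d <- d[d != 0]
  if (!length(d))
    stop("all paired differences are zero: the signed-rank statistic is ",
         "undefined")
  n <- length(d)
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25L && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, exact = exact, correct = !exact,
    conf.int = TRUE, conf.level = conf.level))
  r <- rank(abs(d))
  vPos <- sum(r[d > 0])
  vNeg <- sum(r[d < 0])
  list(V = vPos, VLesser = min(vPos, vNeg), p = wt$p.value,
       ci = unname(wt$conf.int), medianDifference = unname(wt$estimate),
       nPairs = n, exact = exact)
}
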