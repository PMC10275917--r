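#' Centred and scaled log song position
#'
#' The habituation analysis log-transforms song position (natural log,
#' positions starting at 1) and then centres and scales it, as all
#' predictors are. The simulator and the fitter share this one utility
#' so that parameter-recovery is exact in expectation: by default the
#' reference distribution is the vector itself (the observed positions).
#'
#' @param position integer song positions (>= 1).
#' @param reference positions defining the centring/scaling distribution
#'   (default: `position` itself).
#' @return numeric vector, `(log(position) - mean(log(reference))) /
#'   sd(log(reference))`.
#' @export
scaledLogPosition <- function(position, reference = position) {
  if (any(position < 1)) stop("positions must be >= 1")
  (log(position) - mean(log(reference))) / stats::sd(log(reference))
}

checkSeparation <- function(est, se) {
  any(!is.finite(se)) || any(abs(est) > 10) || any(se > 50)
}

glmmCoefTable <- function(fit, conf.level = 0.95) {
  co <- as.data.frame(summary(fit)$coefficients)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  data.frame(term = rownames(co), estimate = est, se = se,
             ciLower = est - z * se, ciUpper = est + z * se,
             backTransformed = inverseLogit(est),
             backLower = inverseLogit(est - z * se),
             backUpper = inverseLogit(est + z * se),
             zValue = co[, "z value"], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Fit the habituation/dishabituation model of female vocal response
#'
#' Binomial mixed model of the per-song binary response as a function of
#' centred-and-scaled log song position, a song-type-switch indicator
#' (bouts preceded by another song-type bout, with silence-preceded
#' bouts as the reference level), their interaction, and a random
#' intercept per female. Estimated by Laplace-approximate maximum
#' likelihood (lme4); per-song Bernoulli rows are aggregated to binomial
#' counts per female x bout-category x position, which leaves the
#' likelihood unchanged. A negative log-position coefficient is
#' habituation; a positive interaction is partial response recovery
#' (dishabituation) after a switch.
#'
#' @param responses data.frame with columns `femaleId`, `precededBy`
#'   (`"silence_gap"`/`"type_switch"`), `position` (>= 1), `response`
#'   (0/1), e.g. from [scoreResponses()] or [simulateResponses()].
#' @param conf.level confidence level of the Wald CIs (default 0.95).
#' @return list with `coefficients` (data.frame: term, logit-scale
#'   estimate, Wald CI, back-transformed estimate and endpoint-wise CI,
#'   Z), `femaleSD` and `femaleVariance` (random-intercept), `nObs`
#'   (Bernoulli observations), `separation` flag, `method`, and the
#'   fitted `model`. Terms are named `(Intercept)`, `switch`,
#'   `logPosition`, `logPosition:switch`.
#' @export
fitHabituationModel <- function(responses, conf.level = 0.95) {
  need <- c("femaleId", "precededBy", "position", "response")
  stopifnot(all(need %in% names(responses)))
  d <- responses
  d$logPosition <- scaledLogPosition(d$position)
  levs <- intersect(c("silence_gap", "type_switch"), unique(d$precededBy))
  oneLevel <- length(levs) < 2L
  if (oneLevel)
    warning("only one preceded-by level present (", levs,
            "): switch terms dropped")
  d$switch <- as.integer(d$precededBy == "type_switch")
  agg <- stats::aggregate(response ~ femaleId + switch + position +
                            logPosition, data = d,
                          FUN = function(x) c(succ = sum(x),
                                              fail = length(x) - sum(x)))
  agg <- cbind(agg[, c("femaleId", "switch", "position", "logPosition")],
               succ = agg$response[, "succ"], fail = agg$response[, "fail"])
  form <- if (oneLevel)
    cbind(succ, fail) ~ logPosition + (1 | femaleId)
  else
    cbind(succ, fail) ~ logPosition * switch + (1 | femaleId)
  fit <- lme4::glmer(form, data = agg, family = stats::binomial(),
                     control = lme4::glmerControl(
                       check.response.not.const = "ignore"))
  tab <- glmmCoefTable(fit, conf.level)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sep <- checkSeparation(tab$estimate, tab$se)
  if (sep)
    warning("possible complete separation: estimates flagged; no ",
            "penalized refit is attempted")
  list(coefficients = tab, femaleSD = vc$sdcor[1L],
       femaleVariance = vc$vcov[1L], nObs = nrow(responses),
       separation = sep,
       method = "binomial GLMM, Laplace approximation (lme4::glmer)",
       model = fit)
}

scaleCentre <- function(x, name) {
  if (stats::sd(x) == 0)
    stop("predictor '", name, "' has zero variance")
  as.numeric(scale(x))
}

#' Fit the female preference model on bout-level responses
#'
#' Binomial mixed model of the number of song-type bouts with vs.
#' without female vocal response per playback song type, as a function
#' of the song's acoustic traits (vocal consistency, song rate, trill
#' length — centred and scaled), with a random intercept per female.
#'
#' @param boutTable data.frame, one row per song type per trial, with
#'   columns `femaleId`, `successes`, `failures` and the predictor
#'   columns.
#' @param predictors character vector of predictor column names
#'   (default `c("consistency", "songRate", "trillLength")`).
#' @param conf.level confidence level of the Wald CIs (default 0.95).
#' @return Same structure as [fitHabituationModel()].
#' @export
fitPreferenceModel <- function(boutTable,
                               predictors = c("consistency", "songRate",
                                              "trillLength"),
                               conf.level = 0.95) {
  stopifnot(all(c("femaleId", "successes", "failures") %in%
                  names(boutTable)),
            all(predictors %in% names(boutTable)))
  d <- boutTable
  for (p in predictors) d[[p]] <- scaleCentre(d[[p]], p)
  form <- stats::as.formula(paste(
    "cbind(successes, failures) ~",
    if (length(predictors)) paste(predictors, collapse = " + ") else "1",
    "+ (1 | femaleId)"))
  fit <- lme4::glmer(form, data = d, family = stats::binomial())
  tab <- glmmCoefTable(fit, conf.level)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sep <- checkSeparation(tab$estimate, tab$se)
  if (sep)
    warning("possible complete separation: estimates flagged; no ",
            "penalized refit is attempted")
  list(coefficients = tab, femaleSD = vc$sdcor[1L],
       femaleVariance = vc$vcov[1L], nObs = nrow(d), separation = sep,
       method = "binomial GLMM, Laplace approximation (lme4::glmer)",
       model = fit)
}

#' Predicted response probability from habituation coefficients
#'
#' Plug-in predicted probability of a female vocal response at a given
#' song position, for silence-preceded or switch-preceded bouts, from
#' logit-scale coefficients (random intercept at zero).
#'
#' @param position song position(s) (>= 1).
#' @param switch 0 for a silence-preceded bout, 1 after a song-type
#'   switch.
#' @param coefficients named numeric vector with elements `intercept`,
#'   `switch`, `logPosition`, `interaction` (logit scale, log-position
#'   on the [scaledLogPosition()] scale).
#' @param reference positions defining the log-position scaling
#'   (default `1:15`).
#' @return Predicted probabilities.
#' @export
predictHabituation <- function(position, switch, coefficients,
                               reference = 1:15) {
  slp <- scaledLogPosition(position, reference)
  inverseLogit(coefficients[["intercept"]] +
                 coefficients[["switch"]] * switch +
                 coefficients[["logPosition"]] * slp +
                 coefficients[["interaction"]] * switch * slp)
}
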