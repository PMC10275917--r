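#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*logLik + 2k + 2k(k+1)/(n-k-1)`, which tends to the
#' ordinary AIC as `n` grows.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @examples
#' aicc(-10, 2, 100) # 24 + 12/97
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc of a fitted model
#'
#' @param model a fitted model with a [stats::logLik()] method.
#' @param n sample size; defaults to the `nobs` attribute of the
#'   log-likelihood.
#' @return The AICc value.
#' @export
aiccOf <- function(model, n = NULL) {
  ll <- stats::logLik(model)
  if (is.null(n)) n <- attr(ll, "nobs")
  aicc(as.numeric(ll), attr(ll, "df"), n)
}

#' Multimodel inference: AICc ranking, full averaging and importance
#'
#' Ranks candidate models by AICc, forms the model-averaging set from
#' all models within `deltaCut` AICc units of the best, and computes
#' Akaike weights `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` over
#' that set. Averaged coefficients use full (zero-substitution)
#' averaging: a model that omits a term contributes a coefficient of 0.
#' The relative importance of a variable is the summed weight of the
#' models in the averaging set that contain it. All models within
#' `reportCut` (default 7) are listed in the ranking table.
#'
#' @param candidates named list; each element is a list with elements
#'   `aicc` (number) and `coefficients` (named numeric vector).
#' @param deltaCut delta-AICc threshold for the averaging set
#'   (default 2).
#' @param reportCut delta-AICc threshold for the report table
#'   (default 7).
#' @return list with `table` (data.frame: model, aicc, delta, weight —
#'   NA outside the averaging set — and inAverageSet, restricted to
#'   `delta < reportCut`), `averagedCoefficients` (named numeric),
#'   `relativeImportance` (named numeric in \[0, 1\]).
#' @examples
#' cands <- list(
#'   m1 = list(aicc = 100.0, coefficients = c(a = 1)),
#'   m2 = list(aicc = 101.0, coefficients = c(a = 0.8, b = 0.1)),
#'   m3 = list(aicc = 104.0, coefficients = c(b = 0.5)))
#' modelAverage(cands)$relativeImportance
#' @export
modelAverage <- function(candidates, deltaCut = 2, reportCut = 7) {
  if (!length(candidates)) stop("empty candidate set")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("m", seq_along(candidates))
  a <- vapply(candidates, function(c) c$aicc, numeric(1))
  delta <- a - min(a)
  inSet <- delta < deltaCut
  w <- exp(-delta / 2) * inSet
  w <- w / sum(w)
  terms <- unique(unlist(lapply(candidates,
                                function(c) names(c$coefficients))))
  avg <- stats::setNames(numeric(length(terms)), terms)
  imp <- stats::setNames(numeric(length(terms)), terms)
  for (i in seq_along(candidates)) {
    if (!inSet[i]) next
    co <- candidates[[i]]$coefficients
    present <- terms %in% names(co)
    avg[present] <- avg[present] + w[i] * co[terms[present]]
    imp[present] <- imp[present] + w[i]
  }
  ord <- order(delta)
  tab <- data.frame(model = names(candidates)[ord], aicc = a[ord],
                    delta = delta[ord],
                    weight = ifelse(inSet[ord], w[ord], NA_real_),
                    inAverageSet = inSet[ord], stringsAsFactors = FALSE,
                    row.names = NULL)
  tab <- tab[tab$delta < reportCut, , drop = FALSE]
  list(table = tab, averagedCoefficients = avg, relativeImportance = imp)
}

#' Variance inflation factors of a design matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from regressing column `j`
#' on all other columns (with intercept). Variables with VIF above
#' `threshold` (default 3) are flagged as collinear.
#'
#' @param X numeric matrix or data.frame of explanatory variables
#'   (no intercept column).
#' @param threshold collinearity flag threshold (default 3).
#' @return data.frame with columns `variable`, `vif`, `flagged`.
#' @examples
#' vif(cbind(a = rnorm(50), b = rnorm(50)))
#' @export
vif <- function(X, threshold = 3) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2L)
    return(data.frame(variable = colnames(X), vif = 1, flagged = FALSE))
  v <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = colnames(X), vif = v, flagged = v > threshold,
             stringsAsFactors = FALSE)
}

#' All-subsets model selection for the preference model
#'
#' Fits the preference GLMM for every subset of the candidate acoustic
#' predictors (including the intercept-only model), ranks the fits by
#' AICc, and returns the full-average model over the delta-AICc < 2 set
#' with per-variable relative importance.
#'
#' @param boutTable as in [fitPreferenceModel()].
#' @param predictors candidate predictor columns.
#' @param ... passed to [modelAverage()].
#' @return list as returned by [modelAverage()], plus `fits` (the
#'   per-subset [fitPreferenceModel()] results).
#' @export
preferenceModelSelection <- function(boutTable,
                                     predictors = c("consistency",
                                                    "songRate",
                                                    "trillLength"),
                                     ...) {
  subsets <- unlist(lapply(0:length(predictors), function(k)
    utils::combn(predictors, k, simplify = FALSE)), recursive = FALSE)
  fits <- list()
  cands <- list()
  for (s in subsets) {
    nm <- if (length(s)) paste(s, collapse = "+") else "(null)"
    f <- fitPreferenceModel(boutTable, predictors = s)
    fits[[nm]] <- f
    co <- stats::setNames(f$coefficients$estimate, f$coefficients$term)
    cands[[nm]] <- list(aicc = aiccOf(f$model, n = f$nObs),
                        coefficients = co)
  }
  out <- modelAverage(cands, ...)
  out$fits <- fits
  out
}
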