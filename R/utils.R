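#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so
#' seeded generators are reproducible without disturbing the global
#' stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Inverse logit (logistic) transform
#'
#' Back-transforms a logit-scale estimate to a probability:
#' `1 / (1 + exp(-x))`. This is the relationship between the
#' logit-transformed and back-transformed columns of a binomial
#' mixed-model coefficient table.
#'
#' @param x numeric, logit-scale value(s).
#' @return Probabilities in (0, 1).
#' @examples
#' inverseLogit(0)       # 0.5
#' inverseLogit(-1.406)  # ~0.197
#' @export
inverseLogit <- function(x) stats::plogis(x)

rmsLevel <- function(x) sqrt(mean(x^2))
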