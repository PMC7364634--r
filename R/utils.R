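#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the prior
#' RNG state, so generators are pure functions of (spec, seed) without
#' disturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

#' Arousal state labels
#'
#' The four on-line scored arousal states, in the package's canonical order.
#' `ARTEFACT` marks epochs removed by quality control.
#'
#' @return character vector of state names.
#' @export
arousal_states <- function() c("WAKE", "THETA_WAKE", "NREM", "REM")
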