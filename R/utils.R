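#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the global generator, evaluates
#' `expr`, and restores the state on exit. All stochastic stages in the
#' package run through this so a single integer seed fully determines their
#' output without clobbering the user's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic, stays below 2^31 - 1 so it is always a valid R integer.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 1009 + h) %% 2147483629L)
}

#' Percentage of a count, rounded for reporting
#'
#' @param events event count.
#' @param n denominator.
#' @param digits decimal places (default 1, the usual reporting precision).
#' @return numeric percentage.
#' @export
#' @examples
#' percent(61, 258)  # 23.6
percent <- function(events, n, digits = 1) {
  stopifnot(n > 0, events >= 0)
  round(100 * events / n, digits)
}

# validation failures get a condition class so the CLI can map them to
# a distinct exit code
stop_param <- function(...) {
  stop(structure(
    class = c("ntcp_validation_error", "error", "condition"),
    list(message = paste0(...), call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
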