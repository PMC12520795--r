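#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores whatever state existed before the call, so library code never
#' clobbers a user's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Fan a global pipeline seed out to per-stage seeds. A fixed odd multiplier
# keeps the streams distinct; the modulus keeps the result a valid 32-bit
# R integer so stages can be re-run in isolation from their logged seed.
stage_seed <- function(seed, stage) {
  offsets <- c(
    landscape = 11L, occurrences = 23L, effort = 31L, pa = 47L,
    splits = 59L, fit = 67L, importance = 79L, projection = 89L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
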