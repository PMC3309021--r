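#' Round half away from zero
#'
#' Reporting convention for effective population sizes: 0.5 always rounds
#' up (75611.5 -> 75612), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run an expression under a locally-seeded RNG without disturbing the
# caller's random state. `seed = NULL` leaves the global RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive per-stage seeds from one top-level seed
#'
#' A single integer seed deterministically yields one sub-seed per named
#' analysis stage, so that one number reproduces a whole report bundle.
#'
#' @param seed integer scalar.
#' @param stages character vector of stage names.
#' @return named integer vector of seeds, all below 2^31.
#' @export
derive_seeds <- function(seed, stages) {
  stopifnot(length(seed) == 1, is.finite(seed))
  s <- with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, length(stages)))
  names(s) <- stages
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
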