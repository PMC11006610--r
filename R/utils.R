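# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package accept `seed = NULL` (use the
#' current RNG stream) or an integer seed; when a seed is given the global
#' RNG state is restored afterwards so that seeded calls do not perturb the
#' caller's stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed for a named pipeline stage
#'
#' One global seed expands into per-stage seeds so that any stage can be
#' re-run in isolation with the same draws. The derivation is a fixed
#' integer hash of the stage name folded into the parent seed, kept below
#' 2^31 - 1.
#'
#' @param seed parent integer seed or `NULL` (returns `NULL`).
#' @param stage character stage label.
#' @return integer seed or `NULL`.
#' @export
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629)
}

# round() uses banker's rounding; the resampling arithmetic in the effort
# standardization follows the conventional half-up rule instead so that
# targets like 0.5 * an odd count are stable across platforms.
round_half_up <- function(x) floor(x + 0.5)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
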