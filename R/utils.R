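#' Round half away from zero
#'
#' Deterministic round-half-up used when converting a target sparsity into an
#' integer edge count, so that e.g. 0.25 * 2278 = 569.5 always becomes 570
#' regardless of the platform's banker's rounding.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Every randomized stage draws from a named substream of the master seed so
#' that stages are independently reproducible.  The derived value is a
#' positive integer below 2^31.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the substream.
#' @return a single integer.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  val <- (abs(seed) %% 2147483647) * 48271 + h * 69621 + 1
  as.integer(val %% 2147483647L)
}

fail_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}
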