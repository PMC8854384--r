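#' Derive independent integer seeds from a master seed
#'
#' Deterministically fans one master seed out into `n` substream seeds, so
#' per-subject or per-stage randomness can be reproduced independently of the
#' order in which subjects are simulated.
#'
#' @param seed master integer seed.
#' @param n number of substream seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# abort with a consistent class so tests can assert on fluctnet errors
abort_fluctnet <- function(msg, ...) {
  rlang::abort(message = msg, class = "fluctnet_error", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
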