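#' Derive a reproducible child seed from a master seed
#'
#' Deterministically maps a master seed plus integer indices (subject, run,
#' stream, ...) to a new seed in [1, 2^31 - 2], so that every stochastic
#' component of a simulated study draws from its own stream while the whole
#' study remains reproducible from one integer.
#'
#' @param seed master seed (single integer).
#' @param ... further integer indices identifying the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in idx) {
    # Knuth-style multiplicative mix, kept in double precision below 2^31
    x <- (x * 48271 + as.double(k) * 9349 + 1) %% 2147483647
  }
  as.integer(x %% 2147483645 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
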