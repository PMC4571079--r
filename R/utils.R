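#' Derive a reproducible stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from one master seed plus a stage label (and optional
#' index), so any stage can be replayed in isolation. The derivation is a
#' small multiplicative congruential hash over the label characters; the
#' result always lies in `[1, 2^31 - 1]` so it is a valid R seed.
#'
#' @param seed master seed (integer).
#' @param ... stage labels: character strings and/or integers.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.double(seed) %% m
  for (p in list(...)) {
    v <- if (is.character(p)) {
      u <- utf8ToInt(p)
      sum(u * seq_along(u))
    } else {
      as.double(p)
    }
    h <- (h * 48271 + abs(v) + 1) %% m
  }
  as.integer(h) + 1L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
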