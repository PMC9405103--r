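#' Derive a reproducible sub-seed from a master seed and context tags
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed plus a string path (species id, procedure, replicate index, ...), so
#' subsets of an experiment can be rerun bit-identically without replaying
#' the full random stream.
#'
#' The hash is a plain polynomial-rolling hash over the UTF-8 bytes of the
#' concatenated tags, folded into the master seed modulo 2^31 - 1 (so the
#' result is always a valid, positive R integer seed).
#'
#' @param master integer master seed.
#' @param ... context tags (coerced to character).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  tags <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                       character(1)), collapse = "/")
  h <- abs(as.numeric(master)) %% m
  for (b in utf8ToInt(tags)) {
    h <- (h * 31 + b) %% m # stays < 2^36, exact in doubles
  }
  as.integer(h %% (m - 2) + 1)
}

# Run expr under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
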