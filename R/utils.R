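#' Derive a per-trial random seed from a master seed and trial counter
#'
#' Counter-based mixing keeps trial substreams independent of the order in
#' which trials are simulated: the seed for trial `index` depends only on
#' `(master_seed, index)`. The result is always in `[1, 2^31 - 2]` so it is a
#' valid argument for [set.seed()].
#'
#' @param master_seed Integer master seed for the whole run.
#' @param index Non-negative integer trial counter.
#' @return A single integer seed.
#' @export
mix_seed <- function(master_seed, index) {
  stopifnot(length(master_seed) == 1L, length(index) == 1L,
            is.finite(master_seed), is.finite(index), index >= 0)
  m <- as.double(master_seed) %% 2147483647
  i <- as.double(index) %% 2147483647
  # combine in 16-bit halves so every product stays well below 2^53
  x <- (m %% 65536) * 32771 + floor(m / 65536) * 7919 +
    (i %% 65536) * 40503 + floor(i / 65536) * 104729 + 12345
  x <- x %% 2147483629
  # two avalanche rounds: without them consecutive indices give seeds in
  # arithmetic progression, which leaves visible structure in the streams
  for (r in 1:2) {
    x <- bitwXor(as.integer(x), bitwShiftR(as.integer(x), 15))
    x <- ((x %% 65536) * 49537 + (x %/% 65536) * 28411 + 7129) %% 2147483629
  }
  as.integer(x %% 2147483645) + 1L
}

# positive half-cosine transient: peak `amp` at `center`, support width `width`
half_wave <- function(time, amp, center, width) {
  u <- (time - center) / width
  out <- numeric(length(time))
  inside <- abs(u) <= 0.5
  out[inside] <- amp * cos(pi * u[inside])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
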