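# Internal helpers: deterministic string hashing and seed substreams.
# All randomness in the package flows from one user seed through named
# substreams so that independent stages draw independent, reproducible
# random numbers.

# 32-bit FNV-1a over the UTF-8 bytes of a string, computed in double
# arithmetic (the multiply is split into 16-bit halves to stay exact).
fnv1a32 <- function(x, seed = 0L) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- (2166136261 + as.numeric(seed)) %% 4294967296
  for (b in utf8ToInt(x)) {
    h <- bitwXor64(h, b %% 256)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# xor of two non-negative doubles < 2^32
bitwXor64 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  as.numeric(hi) * 65536 + as.numeric(lo)
}

# Vectorized string hash in [0, 2^31): used for fold hashing and
# validation-split assignment.
hash_strings <- function(x, seed = 0L) {
  vapply(x, function(s) fnv1a32(s, seed) %% 2147483648, numeric(1),
         USE.NAMES = FALSE)
}

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' Independent pipeline stages (data generation, model initialization,
#' batch shuffling, the combination sweep, ...) each draw their seed from
#' the single run seed via a named substream, so that changing one stage's
#' consumption of random numbers cannot perturb another stage.
#'
#' @param seed Integer master seed.
#' @param name Character stream name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, name) {
  as.integer(fnv1a32(as.character(name), seed = as.integer(seed)) %% 2147483648)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x <= 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

# Mix a vector of non-negative integers into one deterministic 31-bit id.
# Used by the fingerprint to hash atom-environment invariant tuples
# without string construction.
hash_ints <- function(v) {
  h <- 2166136261
  for (b in v) {
    h <- bitwXor64(h, b %% 4294967296)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h %% 2147483648
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
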