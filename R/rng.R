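# Seeded, stream-separated RNG for the synthetic generators.
#
# Each generator draws from a stream derived from (seed, stream name), so
# adding a new generator (or reordering calls) never perturbs the random
# numbers another generator sees.

# 32-bit FNV-1a hash of a string, kept positive and below 2^31.
.hash32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

.stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((as.double(seed) * 48271 + .hash32(name)) %% .Machine$integer.max)
}

# Evaluate `expr` under a derived RNG stream, restoring global RNG state.
with_stream <- function(seed, name, expr) {
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
  set.seed(.stream_seed(seed, name))
  expr
}
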