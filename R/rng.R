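# Counter-based keyed random number generation.
#
# The random permutation stream must satisfy a strong contract: element i
# depends only on (seed, i), never on how many elements were generated
# before it, so that any chunking of indices 1..B-1 across workers yields
# exactly the serial stream.  A counter-based construction gives this for
# free: each 32-bit variate is an avalanche hash (the MurmurHash3
# finalizer) of a counter derived from (seed, permutation index, draw
# index).  All arithmetic is done modulo 2^32 in doubles (exact: every
# intermediate stays below 2^53).

.u32_xor <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

.u32_mul <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  (((ah * b) %% 65536) * 65536 + al * b) %% 4294967296
}

# MurmurHash3 32-bit finalizer; a bijection on [0, 2^32) with full
# avalanche.  Vectorized over a numeric vector of 32-bit values.
.fmix32 <- function(x) {
  x <- .u32_xor(x, x %/% 65536)      # x ^= x >> 16
  x <- .u32_mul(x, 2246822507)       # x *= 0x85ebca6b
  x <- .u32_xor(x, x %/% 8192)       # x ^= x >> 13
  x <- .u32_mul(x, 3266489909)       # x *= 0xc2b2ae35
  .u32_xor(x, x %/% 65536)           # x ^= x >> 16
}

# Matrix of uniforms in [0, 1): one row per stream index, `ndraws`
# 53-bit-resolution variates per row, each built from two 32-bit hashes.
.keyed_uniforms <- function(seed, indices, ndraws) {
  h0 <- .fmix32(seed %% 4294967296)
  hi <- .fmix32(.u32_xor(rep(h0, length(indices)),
                         (indices * 2654435769) %% 4294967296))
  cnt <- outer(hi, seq_len(2 * ndraws) * 968665207, `+`) %% 4294967296
  v <- matrix(.fmix32(as.vector(cnt)), nrow = length(indices))
  odd <- seq(1L, 2L * ndraws, by = 2L)
  (v[, odd, drop = FALSE] * 2097152 +
     v[, odd + 1L, drop = FALSE] %/% 2048) / 9007199254740992
}
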