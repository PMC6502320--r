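#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; surveillance reports round
#' half up. `round_half_up(0.5) == 1`, `round_half_up(1.25, 1) == 1.3`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small deterministic seed derivation: keeps every derived seed a valid
# 32-bit integer and distinct across (stream, substream) pairs.
derive_seed <- function(seed, stream, substream = 0L) {
  as.integer((as.double(seed) + 104729 * stream + 7919 * substream) %%
               .Machine$integer.max)
}

# FNV-1a 32-bit hash of a string, hex-encoded; used for config provenance.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
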