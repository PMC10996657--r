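#' Round half away from zero
#'
#' Rounds to the nearest integer with exact halves going up (0.5 -> 1,
#' 137.5 -> 138), the convention used throughout for member counts. Base
#' `round()` rounds half to even and would give 137.5 -> 138 but 0.5 -> 0.
#'
#' @param x numeric vector (assumed non-negative in this package's usage).
#' @return integer vector.
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Derive a stream-specific seed from a master seed
#'
#' Each source of randomness (wiring, assembly selection, spike patterns,
#' background currents, cue selection) gets its own substream so that one can
#' be varied while the others are held fixed.
#'
#' @param seed master integer seed.
#' @param stream character label of the randomness source.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629L)
}

#' Hash a configuration for manifests and checkpoint compatibility checks
#'
#' A dependency-free FNV-1a style hash over the deparsed object; stable for
#' identical configurations within a package version.
#'
#' @param x any serializable R object.
#' @return hex string.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
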