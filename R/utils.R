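# Small internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' FNV-1a hash of an R object
#'
#' Stable content hash used to stamp study reports so that a report can be
#' traced back to the exact configuration that produced it.  Operates on the
#' canonical JSON serialization of the object, so it is independent of the
#' R session.
#'
#' @param x Any jsonlite-serializable R object.
#' @return A 8-character lowercase hex string.
#' @export
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- as.integer(charToRaw(as.character(json)))
  # 32-bit FNV-1a, done in double arithmetic to avoid integer overflow
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor with a byte only touches the low 8 bits
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)), sprintf("%04x", as.integer(h %% 65536)))
}

# Derive a child RNG seed from a master seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483629) + 1L
}

# seconds -> sample index (0-based), half-open window convention
sec_to_sample <- function(t, rate) as.integer(floor(t * rate + 0.5))

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}
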