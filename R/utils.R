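#' @keywords internal
"_PACKAGE"

# Round to nearest integer, halves away from zero (so 0.5 -> 1, -0.5 -> -1).
# Base round() uses round-half-to-even, which is not how published integer
# weights are conventionally produced.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a reproducible child seed from a parent seed and a stage label.
# Keeps all derived seeds in the positive 31-bit integer range.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == floor(x)
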