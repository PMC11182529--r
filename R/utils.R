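# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonicalise a pair of drug ids: lexicographically smaller id first.
# Pair order matters downstream (the structure embedding concatenates the
# two branches in a fixed order), so every sample is stored canonically.
canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(i = a, j = b)
}

# Unique integer code for an unordered pair 1 <= i < j <= n.
pair_code <- function(i, j, n) (i - 1) * n + j

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_ddi <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ddigcl_error")))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
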