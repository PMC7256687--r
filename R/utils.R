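# Internal helpers shared across modules.

# Deterministic seed expansion: one root seed fans out to per-entity
# substream seeds. Linear congruential step modulo the Mersenne prime
# 2^31 - 1 keeps every derived seed a valid 32-bit R integer.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in idx) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# Rolling max/min over a fixed-width window via a dyadic sparse table:
# O(n log w), no compiled code. Returns the max (or min) over each
# window of `width` consecutive samples; result[i] covers
# x[i .. i+width-1], length n - width + 1.
rollExtreme <- function(x, width, op = c("max", "min")) {
  op <- match.arg(op)
  f <- if (op == "max") pmax else pmin
  n <- length(x)
  stopifnot(width >= 1L, width <= n)
  cur <- x
  span <- 1L
  while (2L * span <= width) {
    cur <- f(cur[seq_len(n - span)], cur[seq_len(n - span) + span])
    span <- 2L * span
    n <- length(cur)
  }
  # cur[i] now covers x[i .. i+span-1]; combine two overlapping spans
  rest <- width - span
  if (rest == 0L) return(cur)
  f(cur[seq_len(length(cur) - rest)], cur[seq_len(length(cur) - rest) + rest])
}

# Pretty percentage for messages
fmtPct <- function(x) sprintf("%.1f%%", 100 * x)
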