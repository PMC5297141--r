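# Independent brute-force oracle for the two-boundary classification rule.
# At every attempt it recomputes the running extrema from scratch over the
# trajectory slice since the last signal (O(n^2)), instead of maintaining
# running state like the implementation. States: 0 inconclusive, 1 proficient,
# -1 nonproficient.
oracle_states <- function(outcomes, constants) {
  s <- constants$s
  values <- c(0, cumsum(ifelse(outcomes == 1L, 1 - s, -s)))
  n <- length(outcomes)
  states <- integer(n)
  state <- 0L
  ref <- 1L  # index into values (1 = C_0) where the extrema window starts
  for (k in seq_len(n)) {
    window <- values[ref:(k + 1L)]
    if (max(window) - values[k + 1L] >= 2 * constants$H0) {
      state <- 1L
      ref <- k + 1L
    } else if (values[k + 1L] - min(window) >= 2 * constants$H1) {
      state <- -1L
      ref <- k + 1L
    }
    states[k] <- state
  }
  states
}

# Per-attempt states implied by a segment table.
segment_states <- function(segments, n) {
  if (nrow(segments) == 0L) return(integer(0))
  code <- c(inconclusive = 0L, proficient = 1L, nonproficient = -1L)
  unname(rep(code[segments$state],
             segments$end_attempt - segments$start_attempt + 1L))
}

paper_constants <- function() cusum_constants(cusum_params(0.1, 0.2, 0.1, 0.1))

# All 2^len outcome sequences of a given length, as rows of a matrix.
all_sequences <- function(len) {
  m <- as.matrix(expand.grid(rep(list(0:1), len)))
  storage.mode(m) <- "integer"
  m
}
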