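# Small shared fixtures, built in code at test time.

tinyScaffold <- function() {
  LibraryScaffold("tiny", list(
    constantSegment("ACG", "c1"),
    randomSegment(2L, label = "r1"),
    constantSegment("T", "c2")))
}

# scaffold with >= 35 bp randomized prefix, used for read-linking tests
keyedScaffold <- function(tail = 10L) {
  LibraryScaffold("keyed", list(
    randomSegment(40L, label = "key"),
    constantSegment("GCGTGGGCG", "site"),
    randomSegment(tail, label = "tail")))
}

# pure position-weight oracle (no motifs): exactly additive per position
linearOracle <- function(scaffold, sd = 0.05, seed = 99L) {
  L <- scaffoldLength(scaffold)
  set.seed(seed)
  pw <- matrix(rnorm(4L * L, sd = sd), 4L, L)
  pw[, !randomizedMask(scaffold)] <- 0
  GroundTruthModel(pw)
}

oracleScorer <- function(model) {
  function(seqs) trueActivity(model, seqs)[, "uninduced"]
}

# reference quadratic-time global alignment cost, kept independent of
# the compiled implementation
nwReference <- function(a, b, gap = 5L, mismatch = 1L) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  prev <- (0:m) * gap
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i * gap
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j] + (A[i] != B[j]) * mismatch,
                         prev[j + 1L] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1L]
}
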