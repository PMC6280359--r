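# Independent oracles used across the suite: brute-force path
# enumeration for the profile HMM, exhaustive sequon scanning, and small
# constructors for toy profiles and alignments.

# Sum (or max) of odds over every state path of the glocal profile HMM,
# by explicit recursion over entry point, profile path and exit. Stays
# independent of the dynamic-programming kernel.
bruteOdds <- function(hmm, codes, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  comb <- if (mode == "sum") `+` else max
  m <- nMatchStates(hmm)
  L <- length(codes)
  eodds <- sweep(hmm@match, 2L, hmm@q, "/")
  tr <- hmm@transitions
  b <- hmm@begin
  recM <- function(k, j) {
    if (k == m) return(1)
    s <- 0
    if (j < L)
      s <- comb(comb(s, tr[k, "MM"] * eodds[k + 1L, codes[j + 1L]] *
                          recM(k + 1L, j + 1L)),
                tr[k, "MI"] * recI(k, j + 1L))
    comb(s, tr[k, "MD"] * recD(k + 1L, j))
  }
  recI <- function(k, j) {
    s <- 0
    if (j < L)
      s <- comb(comb(s, tr[k, "IM"] * eodds[k + 1L, codes[j + 1L]] *
                          recM(k + 1L, j + 1L)),
                tr[k, "II"] * recI(k, j + 1L))
    s
  }
  recD <- function(k, j) {
    if (k == m) return(1)
    s <- 0
    if (j < L)
      s <- comb(s, tr[k, "DM"] * eodds[k + 1L, codes[j + 1L]] *
                     recM(k + 1L, j + 1L))
    comb(s, tr[k, "DD"] * recD(k + 1L, j))
  }
  total <- 0
  for (f in 0:L) {
    if (f < L)
      total <- comb(total,
                    b[["BM"]] * eodds[1L, codes[f + 1L]] * recM(1L, f + 1L))
    total <- comb(total, b[["BD"]] * recD(1L, f))
  }
  unname(total)
}

# Total probability that the model emits a sequence of exactly `L`
# residues, by enumerating profile paths (transition weights only;
# emissions sum to one) and flank splits.
bruteTotalLengthProb <- function(hmm, L) {
  m <- nMatchStates(hmm)
  tr <- hmm@transitions
  b <- hmm@begin
  recM <- function(k, t) {        # in M_k having emitted t profile residues
    if (k == m) return(if (t <= L) L - t + 1 else 0)   # flank splits
    s <- 0
    if (t < L) s <- s + tr[k, "MM"] * recM(k + 1L, t + 1L) +
                       tr[k, "MI"] * recI(k, t + 1L)
    s + tr[k, "MD"] * recD(k + 1L, t)
  }
  recI <- function(k, t) {
    s <- 0
    if (t < L) s <- s + tr[k, "IM"] * recM(k + 1L, t + 1L) +
                       tr[k, "II"] * recI(k, t + 1L)
    s
  }
  recD <- function(k, t) {
    if (k == m) return(if (t <= L) L - t + 1 else 0)
    s <- 0
    if (t < L) s <- s + tr[k, "DM"] * recM(k + 1L, t + 1L)
    s + tr[k, "DD"] * recD(k + 1L, t)
  }
  unname(b[["BM"]] * recM(1L, 1L) + b[["BD"]] * recD(1L, 0L))
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Random small profile for oracle-equivalence tests.
randomToyProfile <- function(m) {
  rdist <- function(n) { x <- runif(n) + 0.05; x / sum(x) }
  match <- t(vapply(seq_len(m), function(i) rdist(20L), numeric(20L)))
  colnames(match) <- AA20
  q <- rdist(20L); names(q) <- AA20
  tnames <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  tr <- matrix(0, max(m - 1L, 1L), 7L, dimnames = list(NULL, tnames))
  for (k in seq_len(max(m - 1L, 1L))) {
    tr[k, c("MM", "MI", "MD")] <- rdist(3L)
    tr[k, c("IM", "II")] <- rdist(2L)
    tr[k, c("DM", "DD")] <- rdist(2L)
  }
  if (m == 1L) tr <- tr[0L, , drop = FALSE]
  bg <- rdist(2L)
  new("ProfileHMM", match = match, q = q, transitions = tr,
      begin = c(BM = bg[1L], BD = bg[2L]), columnMap = seq_len(m))
}

# Profile whose emissions all equal the background, uniform transitions.
nullToyProfile <- function(m) {
  q <- rep(1 / 20, 20L); names(q) <- AA20
  match <- matrix(1 / 20, m, 20L, dimnames = list(NULL, AA20))
  tnames <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  tr <- matrix(rep(c(1/3, 1/3, 1/3, 1/2, 1/2, 1/2, 1/2), each = m - 1L),
               m - 1L, 7L, dimnames = list(NULL, tnames))
  new("ProfileHMM", match = match, q = q, transitions = tr,
      begin = c(BM = 0.5, BD = 0.5), columnMap = seq_len(m))
}

# Exhaustive window scan for N-X-S/T sequons (X != P).
oracleSequons <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  hits <- integer(0)
  for (i in seq_len(max(length(chars) - 2L, 0L))) {
    if (chars[i] == "N" && chars[i + 1L] != "P" &&
        chars[i + 2L] %in% c("S", "T"))
      hits <- c(hits, i)
  }
  hits
}

# Shared small synthetic bundle (computed once per test run).
.fixture_env <- new.env(parent = emptyenv())
smallBundle <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- syntheticConfig(n_per_profile = 15L, n_decoys = 40L, seed = 7L)
    .fixture_env$small <- generateFamily(cfg)
  }
  .fixture_env$small
}
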