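#' ProfileHMM: a profile hidden Markov model of a protein domain
#'
#' Match/insert/delete state model over the 20 amino acids with a map from
#' match states back to the columns of the seed alignment it was built
#' from. Insert states emit the background distribution `q`. Transitions
#' are stored per source state `k = 1..m-1` (columns `MM`, `MI`, `MD`,
#' `IM`, `II`, `DM`, `DD`); the final match/delete state exits to the end
#' state with probability 1. Built with [buildProfile()].
#'
#' @slot match m x 20 matrix of match-state emission probabilities.
#' @slot q Background (null and insert-state) emission distribution.
#' @slot transitions (m-1) x 7 matrix of transition probabilities.
#' @slot begin Length-2 vector `c(BM, BD)`: entry into match/delete state 1.
#' @slot columnMap Integer vector, strictly increasing: the seed-alignment
#'   column of each match state.
#' @export
setClass("ProfileHMM",
  representation(match = "matrix", q = "numeric", transitions = "matrix",
                 begin = "numeric", columnMap = "integer"))

setValidity("ProfileHMM", function(object) {
  m <- nrow(object@match)
  msgs <- character()
  if (m < 1L) msgs <- c(msgs, "profile must have at least one match state")
  if (ncol(object@match) != 20L) msgs <- c(msgs, "emissions must cover 20 residues")
  if (any(abs(rowSums(object@match) - 1) > 1e-9))
    msgs <- c(msgs, "match emissions must sum to 1")
  if (length(object@q) != 20L || abs(sum(object@q) - 1) > 1e-9)
    msgs <- c(msgs, "background q must be a 20-residue distribution summing to 1")
  if (abs(sum(object@begin) - 1) > 1e-9)
    msgs <- c(msgs, "begin transitions must sum to 1")
  if (m > 1L) {
    tr <- object@transitions
    if (nrow(tr) != m - 1L) msgs <- c(msgs, "transitions must have m-1 rows")
    sums <- cbind(rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE]),
                  rowSums(tr[, c("IM", "II"), drop = FALSE]),
                  rowSums(tr[, c("DM", "DD"), drop = FALSE]))
    if (any(abs(sums - 1) > 1e-9))
      msgs <- c(msgs, "each outgoing transition set must sum to 1")
  }
  if (length(object@columnMap) != m ||
      (m > 1L && any(diff(object@columnMap) <= 0L)))
    msgs <- c(msgs, "columnMap must be strictly increasing with one entry per match state")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ProfileHMM Number of match states.
#' @param x,object A `ProfileHMM`.
#' @export
nMatchStates <- function(x) nrow(x@match)

#' @describeIn ProfileHMM Match-state to seed-column map.
#' @export
columnMap <- function(x) x@columnMap

#' @describeIn ProfileHMM Background emission distribution.
#' @export
backgroundFreqs <- function(x) x@q

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM with", nMatchStates(object), "match states",
      sprintf("(seed columns %d..%d)\n",
              min(object@columnMap), max(object@columnMap)))
  cons <- colnames(object@match)[apply(object@match, 1L, which.max)]
  cat("consensus:", substr(paste(cons, collapse = ""), 1L, 60L),
      if (nMatchStates(object) > 60L) "..." else "", "\n")
})

#' EvalueCalibration: Gumbel calibration of profile bit scores
#'
#' Maximum-likelihood Gumbel fit to the bit scores of background-generated
#' sequences, used to convert a bit score `S` into an E-value
#' `E(S) = N * exp(-lambda * (S - mu))`, clamped to `[0, N]`.
#' Built with [calibrateEvalue()].
#'
#' @slot lambda Gumbel slope (per bit), > 0.
#' @slot mu Gumbel location (bits).
#' @slot N Database size the E-value refers to.
#' @slot nRandom Number of calibration sequences scored.
#' @slot seed RNG seed used for the calibration sample.
#' @export
setClass("EvalueCalibration",
  representation(lambda = "numeric", mu = "numeric", N = "numeric",
                 nRandom = "integer", seed = "integer"))

setValidity("EvalueCalibration", function(object) {
  msgs <- character()
  if (object@lambda <= 0) msgs <- c(msgs, "lambda must be positive")
  if (object@nRandom < 100L) msgs <- c(msgs, "nRandom must be >= 100")
  if (object@N < 1) msgs <- c(msgs, "database size N must be >= 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EvalueCalibration", function(object) {
  cat(sprintf("EvalueCalibration: lambda=%.4f /bit, mu=%.2f bits, N=%g (n=%d)\n",
              object@lambda, object@mu, object@N, object@nRandom))
})

#' ConservationProfile: per-column conservation of a sequence group
#'
#' Gap-excluded residue frequencies, occupancy, Shannon information
#' content (bits), and consensus per alignment column for a group of
#' aligned sequences. Built with [columnProfile()].
#'
#' @slot freq ncol x 20 matrix of residue frequencies (rows sum to 1 for
#'   occupied columns; `NA` for empty columns).
#' @slot occupancy Fraction of group sequences with a residue per column.
#' @slot ic Information content per column, `log2(20) - H`, in bits.
#' @slot consensus Consensus residue per column ("" for empty columns).
#' @slot consensusFreq Frequency of the consensus residue.
#' @slot groupSize Number of sequences in the group.
#' @export
setClass("ConservationProfile",
  representation(freq = "matrix", occupancy = "numeric", ic = "numeric",
                 consensus = "character", consensusFreq = "numeric",
                 groupSize = "integer"))

setValidity("ConservationProfile", function(object) {
  msgs <- character()
  nc <- nrow(object@freq)
  if (ncol(object@freq) != 20L) msgs <- c(msgs, "freq must have 20 residue columns")
  if (length(object@occupancy) != nc || length(object@ic) != nc ||
      length(object@consensus) != nc)
    msgs <- c(msgs, "per-column slots must have one entry per column")
  occ <- object@occupancy > 0
  if (any(occ)) {
    if (any(abs(rowSums(object@freq[occ, , drop = FALSE]) - 1) > 1e-9))
      msgs <- c(msgs, "frequencies of occupied columns must sum to 1")
    ics <- object@ic[occ]
    if (any(ics < -1e-9 | ics > log2(20) + 1e-9))
      msgs <- c(msgs, "information content must lie in [0, log2 20]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ConservationProfile Information content (bits) per column.
#' @param x,object A `ConservationProfile`.
#' @export
informationContent <- function(x) x@ic

#' @describeIn ConservationProfile Per-column residue frequency matrix.
#' @export
residueFrequencies <- function(x) x@freq

#' @describeIn ConservationProfile Consensus sequence of the group.
#' @export
consensusResidues <- function(x) x@consensus

setMethod("show", "ConservationProfile", function(object) {
  cat("ConservationProfile over", nrow(object@freq), "columns,",
      object@groupSize, "sequences\n")
  cat(sprintf("mean IC %.2f bits; %d columns with consensus frequency >= 0.9\n",
              mean(object@ic, na.rm = TRUE),
              sum(object@consensusFreq >= 0.9, na.rm = TRUE)))
})
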