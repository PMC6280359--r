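# Forward/Viterbi scoring of sequences against a profile HMM, Gumbel
# E-value calibration, and database search at an E-value cutoff.

# Residues -> integer codes 1..20; unknowns are an error in strict mode,
# otherwise code 0 (score-neutral ambiguity averaging).
encodeSequence <- function(seq, strict = TRUE) {
  chars <- strsplit(as.character(seq), "")[[1L]]
  code <- match(chars, AA_ALPHABET)
  if (anyNA(code)) {
    if (strict)
      stop("illegal residue symbol(s): ",
           paste(unique(chars[is.na(code)]), collapse = ", "))
    code[is.na(code)] <- 0L
  }
  code
}

# Natural-log pieces of the model handed to the C++ kernel.
profileLogs <- function(hmm) {
  tr <- hmm@transitions
  lg <- function(x) ifelse(x > 0, log(x), -Inf)
  list(logE = log(sweep(hmm@match, 2L, hmm@q, "/")),
       lBM = lg(hmm@begin[["BM"]]), lBD = lg(hmm@begin[["BD"]]),
       lMM = lg(tr[, "MM"]), lMI = lg(tr[, "MI"]), lMD = lg(tr[, "MD"]),
       lIM = lg(tr[, "IM"]), lII = lg(tr[, "II"]),
       lDM = lg(tr[, "DM"]), lDD = lg(tr[, "DD"]))
}

#' Score one sequence against a profile HMM
#'
#' Forward-algorithm log-odds bit score against an i.i.d. background null
#' (glocal: the whole profile, local in the sequence), with the Viterbi
#' state path for reference-column mapping. Computation is in log space
#' and is stable for sequences up to at least 10,000 residues.
#'
#' @param hmm A [ProfileHMM-class].
#' @param seq A single protein sequence (character or
#'   [Biostrings::AAString]).
#' @param do_path Also compute the Viterbi path (default `TRUE`).
#' @param strict Error on non-standard residue symbols; when `FALSE` they
#'   are scored as ambiguity-neutral.
#' @return A list: `bitscore` (forward), `viterbi_bits`, and when
#'   `do_path` is set, `path` (per residue: 0 = flank, k = match state k,
#'   -k = insert state k), `start`, `end` (1-based aligned span).
#' @export
scoreSequence <- function(hmm, seq, do_path = TRUE, strict = TRUE) {
  x <- encodeSequence(seq, strict = strict)
  if (length(x) == 0L) stop("sequence must be non-empty")
  lp <- profileLogs(hmm)
  r <- .dp_profile(x, lp$logE, lp$lBM, lp$lBD, lp$lMM, lp$lMI, lp$lMD,
                   lp$lIM, lp$lII, lp$lDM, lp$lDD, do_path)
  out <- list(bitscore = r$forward / log(2),
              viterbi_bits = r$viterbi / log(2))
  if (do_path) {
    out$path <- r$path
    emitted <- which(r$path != 0L)
    out$start <- if (length(emitted)) min(emitted) else NA_integer_
    out$end <- if (length(emitted)) max(emitted) else NA_integer_
  }
  out
}

# Batch forward scores (and optionally paths) for an AAStringSet. Paths
# are posterior-decoded (maximum expected accuracy) by default, which is
# markedly more robust than the single Viterbi path for column mapping;
# `path_method = "viterbi"` gives the raw best path.
scoreSet <- function(hmm, seqs, do_path = FALSE, strict = FALSE,
                     path_method = c("mac", "viterbi"), delta = 0.05) {
  path_method <- match.arg(path_method)
  lp <- profileLogs(hmm)
  lapply(as.character(seqs), function(s) {
    x <- encodeSequence(s, strict = strict)
    r <- .dp_profile(x, lp$logE, lp$lBM, lp$lBD, lp$lMM, lp$lMI, lp$lMD,
                     lp$lIM, lp$lII, lp$lDM, lp$lDD,
                     do_path && path_method == "viterbi")
    if (do_path && path_method == "mac")
      r$path <- .dp_mac_path(x, lp$logE, lp$lBM, lp$lBD, lp$lMM, lp$lMI,
                             lp$lMD, lp$lIM, lp$lII, lp$lDM, lp$lDD,
                             delta)
    r
  })
}

# Maximum-likelihood Gumbel (max-domain) fit; returns c(lambda, mu) with
# lambda = 1/beta. Standard fixed point solved on the scale parameter.
fitGumbel <- function(x) {
  n <- length(x)
  if (n < 2L || sd(x) < 1e-12)
    stop("degenerate score variance: cannot calibrate")
  xbar <- mean(x)
  wmean <- function(beta) {
    y <- -x / beta
    w <- exp(y - max(y))
    sum(x * w) / sum(w)
  }
  f <- function(beta) beta - xbar + wmean(beta)
  beta0 <- sd(x) * sqrt(6) / pi
  lo <- beta0 / 100; hi <- beta0 * 100
  beta <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  y <- -x / beta
  M <- max(y)
  mu <- -beta * (M + log(mean(exp(y - M))))
  c(lambda = 1 / beta, mu = mu)
}

#' Calibrate E-values for a profile by scoring background sequences
#'
#' Scores `n_random` i.i.d. sequences drawn from the profile's background
#' distribution (lengths from the discretised symmetric length model) and
#' fits a Gumbel distribution to the bit scores by maximum likelihood.
#' E-values are then `E(S) = N * exp(-lambda * (S - mu))`, clamped to
#' `[0, N]`.
#'
#' @param hmm A [ProfileHMM-class].
#' @param n_random Number of calibration sequences (>= 100).
#' @param length_model Numeric `c(median, spread)` of calibration sequence
#'   lengths.
#' @param seed Integer RNG seed.
#' @param N Database size the E-values will refer to (number of sequences
#'   to be searched).
#' @return An [EvalueCalibration-class].
#' @export
calibrateEvalue <- function(hmm, n_random = 1000L,
                            length_model = c(213, 15), seed = 1L,
                            N = n_random) {
  if (n_random < 100L) stop("n_random must be >= 100")
  scores <- withSeed(seed, {
    lens <- sampleLengths(n_random, length_model[1L], length_model[2L])
    vapply(lens, function(l) {
      s <- paste(sample(AA_ALPHABET, l, replace = TRUE, prob = hmm@q),
                 collapse = "")
      scoreSequence(hmm, s, do_path = FALSE)$bitscore
    }, numeric(1L))
  })
  fit <- fitGumbel(scores)
  new("EvalueCalibration", lambda = unname(fit["lambda"]),
      mu = unname(fit["mu"]), N = as.numeric(N),
      nRandom = as.integer(n_random), seed = as.integer(seed))
}

#' Convert bit scores to E-values under a calibration
#'
#' @param calibration An [EvalueCalibration-class].
#' @param bitscore Numeric vector of forward bit scores.
#' @return E-values, monotonically decreasing in the bit score, clamped to
#'   `[0, N]`.
#' @export
evalueOf <- function(calibration, bitscore) {
  pmin(calibration@N,
       calibration@N * exp(-calibration@lambda *
                             (bitscore - calibration@mu)))
}

#' Search a protein set for the domain
#'
#' One best (glocal) hit per sequence with forward bit score, calibrated
#' E-value, Viterbi-aligned span and state path. Hits are sorted by
#' E-value (ascending), ties broken by id.
#'
#' @param hmm A [ProfileHMM-class].
#' @param seqs An [Biostrings::AAStringSet] (or named character vector).
#' @param calibration An [EvalueCalibration-class]; its `N` should equal
#'   `length(seqs)`.
#' @param cutoff E-value acceptance threshold (the survey default is
#'   1e-5).
#' @return A data frame with columns `id`, `bitscore`, `evalue`, `start`,
#'   `end`, `pass`, and a list column `path` holding the Viterbi state
#'   path of each sequence.
#' @export
searchDomains <- function(hmm, seqs, calibration, cutoff = 1e-5) {
  if (length(seqs) == 0L)
    return(data.frame(id = character(), bitscore = numeric(),
                      evalue = numeric(), start = integer(),
                      end = integer(), pass = logical(),
                      path = I(list())))
  if (abs(calibration@N - length(seqs)) > 0.5)
    warning("calibration database size N (", calibration@N,
            ") differs from the number of searched sequences (",
            length(seqs), ")")
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
  res <- scoreSet(hmm, seqs, do_path = TRUE)
  bits <- vapply(res, function(r) r$forward / log(2), numeric(1L))
  paths <- lapply(res, `[[`, "path")
  spans <- vapply(paths, function(p) {
    e <- which(p != 0L)
    if (length(e)) c(min(e), max(e)) else c(NA_integer_, NA_integer_)
  }, integer(2L))
  ev <- evalueOf(calibration, bits)
  hits <- data.frame(id = ids, bitscore = bits, evalue = ev,
                     start = spans[1L, ], end = spans[2L, ],
                     pass = ev <= cutoff, path = I(unname(paths)),
                     stringsAsFactors = FALSE, row.names = NULL)
  hits[order(hits$evalue, hits$id), , drop = FALSE]
}

#' Write search hits as TSV
#'
#' @param hits Data frame from [searchDomains()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHits <- function(hits, path) {
  write.table(hits[, c("id", "bitscore", "evalue", "start", "end", "pass")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
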