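# Profile HMM construction from a seed alignment, and JSON serialization.

GAP_CHARS <- c("-", ".")

# Seed alignment -> character matrix, with alphabet and shape checks.
alignmentMatrix <- function(aln) {
  if (is(aln, "AAStringSet") || is(aln, "XStringSet"))
    aln <- as.character(aln)
  if (is.matrix(aln)) {
    mat <- aln
  } else if (is.character(aln)) {
    if (length(unique(nchar(aln))) > 1L)
      stop("alignment rows must all have equal length")
    mat <- do.call(rbind, strsplit(aln, ""))
    rownames(mat) <- names(aln)
  } else stop("unsupported alignment representation")
  bad <- setdiff(unique(as.vector(mat)), c(AA_ALPHABET, GAP_CHARS))
  if (length(bad))
    stop("illegal alignment symbols: ", paste(bad, collapse = ", "))
  mat
}

#' Build a profile HMM from a seed alignment
#'
#' Columns whose residue occupancy is at least `match_occupancy_threshold`
#' (inclusive) become match states. Match emissions are
#' `(counts + pseudocount * q) / (n_residues + pseudocount)` with `q` the
#' background distribution estimated from all seed residues (with a
#' Laplace count of 1 per letter); transitions are estimated from the
#' observed per-row state paths with the same pseudocount weight spread
#' uniformly over each state's outgoing options. The column map records
#' each match state's source column.
#'
#' @param seed Seed alignment: an [Biostrings::AAStringSet] of equal-width
#'   rows (>= 2), a character vector of aligned strings, or a character
#'   matrix.
#' @param match_occupancy_threshold Fraction of rows that must carry a
#'   residue for a column to become a match state.
#' @param pseudocount Smoothing weight for emissions and transitions.
#' @return A [ProfileHMM-class] object.
#' @export
#' @examples
#' aln <- Biostrings::AAStringSet(c(a = "ACDE", b = "ACDE"))
#' hmm <- buildProfile(aln)
#' nMatchStates(hmm)
buildProfile <- function(seed, match_occupancy_threshold = 0.5,
                         pseudocount = 1) {
  mat <- alignmentMatrix(seed)
  if (nrow(mat) < 2L) stop("seed alignment needs at least 2 rows")
  stopifnot(match_occupancy_threshold > 0, match_occupancy_threshold <= 1,
            pseudocount >= 0)
  isres <- !(mat %in% GAP_CHARS)
  dim(isres) <- dim(mat)
  occ <- colMeans(isres)
  match_cols <- which(occ >= match_occupancy_threshold)
  m <- length(match_cols)
  if (m == 0L)
    stop("degenerate seed alignment: no column reaches the occupancy threshold")

  res_counts <- table(factor(mat[isres], levels = AA_ALPHABET))
  q <- (as.numeric(res_counts) + 1) / (sum(res_counts) + 20)
  names(q) <- AA_ALPHABET

  emis <- matrix(0, m, 20, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(m)) {
    col <- mat[, match_cols[k]]
    cnt <- table(factor(col[!(col %in% GAP_CHARS)], levels = AA_ALPHABET))
    emis[k, ] <- (as.numeric(cnt) + pseudocount * q) /
      (sum(cnt) + pseudocount)
  }

  # Transition counts from observed state paths. Residues in non-match
  # columns before the first / after the last match column are treated as
  # sequence flank and ignored.
  tnames <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  cnt <- matrix(0, max(m - 1L, 1L), 7L, dimnames = list(NULL, tnames))
  bcnt <- c(BM = 0, BD = 0)
  nonmatch <- setdiff(seq_len(ncol(mat)), match_cols)
  # number of match columns preceding each non-match column
  prev_match <- findInterval(nonmatch, match_cols)
  for (r in seq_len(nrow(mat))) {
    st <- ifelse(isres[r, match_cols], "M", "D")
    bcnt[paste0("B", st[1L])] <- bcnt[paste0("B", st[1L])] + 1
    if (m > 1L) {
      g <- tabulate(prev_match[isres[r, nonmatch]], nbins = m)
      for (k in seq_len(m - 1L)) {
        if (g[k] == 0L) {
          key <- paste0(st[k], st[k + 1L])
          cnt[k, key] <- cnt[k, key] + 1
        } else {
          cnt[k, paste0(st[k], "I")] <- cnt[k, paste0(st[k], "I")] + 1
          cnt[k, "II"] <- cnt[k, "II"] + g[k] - 1L
          cnt[k, "IM"] <- cnt[k, "IM"] + 1
        }
      }
    }
  }
  # structured transition prior (scaled by the pseudocount weight):
  # match continuation is strongly favoured and gap states prefer to
  # return to the match track, as in standard profile-HMM priors
  pc <- pseudocount
  prior <- c(MM = 0.93, MI = 0.02, MD = 0.05,
             IM = 0.75, II = 0.25, DM = 0.7, DD = 0.3)
  tr <- sweep(cnt, 2L, pc * prior[tnames], "+")
  tr[, c("MM", "MI", "MD")] <- tr[, c("MM", "MI", "MD")] /
    rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE])
  tr[, c("IM", "II")] <- tr[, c("IM", "II")] /
    rowSums(tr[, c("IM", "II"), drop = FALSE])
  tr[, c("DM", "DD")] <- tr[, c("DM", "DD")] /
    rowSums(tr[, c("DM", "DD"), drop = FALSE])
  if (m == 1L) tr <- tr[0L, , drop = FALSE]
  begin <- (bcnt + pc / 2) / sum(bcnt + pc / 2)
  names(begin) <- c("BM", "BD")

  new("ProfileHMM", match = emis, q = q, transitions = tr,
      begin = begin, columnMap = as.integer(match_cols))
}

#' Serialize a profile HMM to versioned JSON
#'
#' @param hmm A [ProfileHMM-class].
#' @param path Output / input file path.
#' @return `writeProfile()` returns `path` invisibly; `readProfile()`
#'   returns the [ProfileHMM-class].
#' @export
writeProfile <- function(hmm, path) {
  obj <- list(format = "epdrsurvey-profile", version = 1L,
              alphabet = AA_ALPHABET,
              match = unname(hmm@match),
              q = unname(hmm@q),
              transitions = unname(hmm@transitions),
              transition_names = colnames(hmm@transitions),
              begin = unname(hmm@begin),
              column_map = hmm@columnMap)
  write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  obj <- read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "epdrsurvey-profile"))
    stop("not an epdrsurvey profile file")
  emis <- matrix(unlist(obj$match), ncol = 20L, byrow = FALSE)
  if (is.matrix(obj$match)) emis <- obj$match
  colnames(emis) <- AA_ALPHABET
  tr <- obj$transitions
  if (!is.matrix(tr)) tr <- matrix(unlist(tr), ncol = 7L)
  if (nrow(emis) == 1L) tr <- matrix(numeric(0), 0L, 7L)
  colnames(tr) <- obj$transition_names
  new("ProfileHMM", match = emis, q = setNames(obj$q, AA_ALPHABET),
      transitions = tr,
      begin = setNames(obj$begin, c("BM", "BD")),
      columnMap = as.integer(obj$column_map))
}
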