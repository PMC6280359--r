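# Per-column conservation: residue frequencies, information content,
# consensus, conserved-column detection, and logo matrices.

#' Per-column conservation profile of a sequence group
#'
#' Residue frequencies are computed over non-gap residues only (occupancy
#' is recorded separately), and information content per column is
#' `IC = log2(20) - H` with `H` the Shannon entropy of the frequency
#' vector, in bits.
#'
#' @param aln Aligned [Biostrings::AAStringSet] / character matrix.
#' @param group Optional subset of row ids (or indices) forming the
#'   group; defaults to all rows.
#' @return A [ConservationProfile-class].
#' @export
#' @examples
#' cp <- columnProfile(Biostrings::AAStringSet(c(a = "AC", b = "AD")))
#' informationContent(cp)
columnProfile <- function(aln, group = NULL) {
  mat <- alignmentMatrix(aln)
  if (!is.null(group)) {
    if (is.character(group)) {
      missing <- setdiff(group, rownames(mat))
      if (length(missing))
        stop("group ids not in alignment: ", paste(missing, collapse = ", "))
      mat <- mat[group, , drop = FALSE]
    } else mat <- mat[group, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop("empty group")
  nc <- ncol(mat)
  freq <- matrix(NA_real_, nc, 20L, dimnames = list(NULL, AA_ALPHABET))
  occupancy <- numeric(nc)
  ic <- rep(NA_real_, nc)
  consensus <- character(nc)
  consensusFreq <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    col <- mat[, j]
    col <- col[!(col %in% GAP_CHARS)]
    occupancy[j] <- length(col) / nrow(mat)
    if (!length(col)) next
    f <- as.numeric(table(factor(col, levels = AA_ALPHABET))) / length(col)
    freq[j, ] <- f
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    ic[j] <- log2(20) - h
    best <- which.max(f)  # ties: first residue in alphabet order
    consensus[j] <- AA_ALPHABET[best]
    consensusFreq[j] <- f[best]
  }
  new("ConservationProfile", freq = freq, occupancy = occupancy, ic = ic,
      consensus = consensus, consensusFreq = consensusFreq,
      groupSize = nrow(mat))
}

#' Columns where a residue is conserved
#'
#' @param profile A [ConservationProfile-class].
#' @param residue Single residue letter (default `"C"`).
#' @param min_freq Minimum gap-excluded frequency (inclusive); the survey
#'   default for "conserved" is 0.9.
#' @return Sorted integer vector of column indices.
#' @export
conservedColumns <- function(profile, residue = "C", min_freq = 0.9) {
  stopifnot(min_freq > 0, min_freq <= 1, residue %in% AA_ALPHABET)
  f <- profile@freq[, residue]
  sort(which(!is.na(f) & f >= min_freq))
}

#' Sequence-logo letter-height matrix
#'
#' Information-scaled heights are `height = f * IC` per column (column
#' sums equal the column's information content); frequency scaling
#' returns the frequencies themselves.
#'
#' @param profile A [ConservationProfile-class].
#' @param scaling `"information"` or `"frequency"`.
#' @return ncol x 20 numeric matrix of letter heights (empty columns are
#'   all zero).
#' @export
logoMatrix <- function(profile, scaling = c("information", "frequency")) {
  scaling <- match.arg(scaling)
  f <- profile@freq
  f[is.na(f)] <- 0
  if (scaling == "frequency") return(f)
  ic <- ifelse(is.na(profile@ic), 0, profile@ic)
  f * ic
}

#' Write a conservation profile (frequencies, IC, logo heights) as TSV
#'
#' Long format: one row per (column, residue) with frequency, occupancy,
#' information content and letter height, consumable by standard logo
#' plotters.
#'
#' @param profile A [ConservationProfile-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeConservation <- function(profile, path) {
  hm <- logoMatrix(profile)
  nc <- nrow(profile@freq)
  long <- do.call(rbind, lapply(seq_len(nc), function(j) {
    f <- profile@freq[j, ]
    keep <- !is.na(f) & f > 0
    if (!any(keep)) return(NULL)
    data.frame(column = j, residue = AA_ALPHABET[keep],
               frequency = unname(f[keep]),
               occupancy = profile@occupancy[j],
               ic = profile@ic[j],
               height = unname(hm[j, keep]),
               stringsAsFactors = FALSE)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
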