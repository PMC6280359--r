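# Reference-column coordinate system: mapping hit residues to seed
# alignment columns, implied alignments, trimming, and redundancy removal.

#' Map a hit's residues to reference alignment columns
#'
#' Uses the hit's Viterbi state path: residues emitted by match state `k`
#' map to the profile's source column `columnMap(hmm)[k]`; insert-state
#' and flank residues are unmapped (`NA`); delete states consume a column
#' with no residue.
#'
#' @param hit One row of the data frame returned by [searchDomains()], or
#'   a raw state-path integer vector.
#' @param hmm The [ProfileHMM-class] the hit was produced with.
#' @return An integer vector with one entry per sequence residue: the
#'   1-based reference column, or `NA` where unmapped.
#' @export
mapToColumns <- function(hit, hmm) {
  path <- if (is.data.frame(hit)) {
    if (nrow(hit) != 1L) stop("pass exactly one hit row")
    hit$path[[1L]]
  } else as.integer(hit)
  if (any(path > nMatchStates(hmm)))
    stop("corrupt hit: state path addresses a match state beyond the profile")
  map <- rep(NA_integer_, length(path))
  mm <- path > 0L
  map[mm] <- columnMap(hmm)[path[mm]]
  if (any(mm) && any(diff(map[mm]) <= 0L))
    stop("corrupt hit: mapped columns are not strictly increasing")
  map
}

#' Arrange mapped sequences into the reference column space
#'
#' Builds a gapped alignment with one column per reference column;
#' insert-state residues (sequence-specific insertions) are dropped, which
#' is the alignment the survey's trimming step works on.
#'
#' @param seqs Sequences ([Biostrings::AAStringSet] or character vector),
#'   named by id.
#' @param maps List of column maps (as from [mapToColumns()] or the
#'   generator truth), parallel to `seqs`.
#' @param ncol Number of reference columns (defaults to the largest mapped
#'   column).
#' @return An aligned [Biostrings::AAStringSet].
#' @export
impliedAlignment <- function(seqs, maps, ncol = NULL) {
  chars <- strsplit(as.character(seqs), "")
  if (is.null(ncol))
    ncol <- max(unlist(lapply(maps, function(m) m[!is.na(m)])), 0L)
  rows <- vapply(seq_along(chars), function(i) {
    row <- rep("-", ncol)
    m <- maps[[i]]
    keep <- !is.na(m)
    row[m[keep]] <- chars[[i]][keep]
    paste(row, collapse = "")
  }, character(1L))
  names(rows) <- names(seqs)
  AAStringSet(rows)
}

#' Trim low-occupancy columns from an alignment
#'
#' Columns whose residue occupancy falls below `threshold` are removed
#' (sequence-specific insertions); an explicit column range can be dropped
#' as well (e.g. a divergent C-terminal block). Returns the trimmed
#' alignment together with the old-to-new column renumbering map.
#'
#' @param aln Aligned [Biostrings::AAStringSet] / character matrix.
#' @param threshold Occupancy threshold in (0, 1]; columns with occupancy
#'   `< threshold` are removed. `0` keeps every column.
#' @param drop_columns Optional integer vector of columns to force-drop.
#' @return A list: `alignment` (trimmed [Biostrings::AAStringSet]) and
#'   `renumbering` (integer vector, old column -> new column, `NA` for
#'   removed columns).
#' @export
trimAlignment <- function(aln, threshold = 0.5, drop_columns = NULL) {
  mat <- alignmentMatrix(aln)
  stopifnot(threshold >= 0, threshold <= 1)
  isres <- !(mat %in% GAP_CHARS)
  dim(isres) <- dim(mat)
  occ <- colMeans(isres)
  keep <- occ >= threshold
  if (!is.null(drop_columns)) keep[drop_columns] <- FALSE
  if (!any(keep))
    stop("degenerate trim: no columns retained")
  renum <- rep(NA_integer_, ncol(mat))
  renum[keep] <- seq_len(sum(keep))
  trimmed <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  out <- AAStringSet(trimmed)
  names(out) <- rownames(mat)
  list(alignment = out, renumbering = renum)
}

# Pairwise match / compared-site counts over an alignment matrix under
# pairwise deletion, via one-hot matrix products; optional integer column
# weights implement bootstrap resampling.
alignmentPairCounts <- function(mat, weights = NULL) {
  n <- nrow(mat)
  L <- ncol(mat)
  if (is.null(weights)) weights <- rep(1, L)
  isres <- !(mat %in% GAP_CHARS)
  dim(isres) <- dim(mat)
  G <- isres * 1
  Gw <- sweep(G, 2L, weights, "*")
  compared <- Gw %*% t(G)
  matches <- matrix(0, n, n)
  for (a in AA_ALPHABET) {
    X <- (mat == a) * 1
    if (!any(X > 0)) next
    Xw <- sweep(X, 2L, weights, "*")
    matches <- matches + Xw %*% t(X)
  }
  list(matches = matches, compared = compared)
}

#' Remove identical and very similar sequences
#'
#' Greedy clustering on pairwise ungapped identity over shared (pairwise
#' deletion) alignment columns. Sequences are visited in deterministic
#' order (ungapped length descending, id ascending); each sequence joins
#' the first retained sequence it matches at `identity_threshold` or
#' above, so the longest member of each cluster is retained.
#'
#' @param aln Aligned [Biostrings::AAStringSet] (e.g. from
#'   [impliedAlignment()]), named by id.
#' @param identity_threshold Fraction in (0, 1]; pairs at or above it are
#'   considered redundant. The survey default is 0.97.
#' @return A list: `retained` (ids kept), `clusters` (data frame `id`,
#'   `representative`, `identity`).
#' @export
deduplicate <- function(aln, identity_threshold = 0.97) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  mat <- alignmentMatrix(aln)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(mat)))
  pc <- alignmentPairCounts(mat)
  ident <- pc$matches / pmax(pc$compared, 1)
  ident[pc$compared == 0] <- 0
  isres <- !(mat %in% GAP_CHARS)
  dim(isres) <- dim(mat)
  lens <- rowSums(isres)
  ord <- order(-lens, ids)
  retained <- integer(0)
  rep_of <- character(length(ids))
  rep_ident <- numeric(length(ids))
  for (i in ord) {
    if (length(retained)) {
      sims <- ident[i, retained]
      j <- which(sims >= identity_threshold)
      if (length(j)) {
        best <- retained[j[which.max(sims[j])]]
        rep_of[i] <- ids[best]
        rep_ident[i] <- max(sims[j])
        next
      }
    }
    retained <- c(retained, i)
    rep_of[i] <- ids[i]
    rep_ident[i] <- 1
  }
  keep_ids <- ids[sort(retained)]
  list(retained = keep_ids,
       clusters = data.frame(id = ids, representative = rep_of,
                             identity = rep_ident,
                             stringsAsFactors = FALSE))
}

#' Fraction of profile match states covered by a column map
#'
#' Incomplete sequences missing a large portion of the domain are
#' filtered by requiring a minimum coverage (survey default 0.6).
#'
#' @param map Column map from [mapToColumns()].
#' @param hmm The [ProfileHMM-class].
#' @return Fraction of match states with a mapped residue.
#' @export
columnCoverage <- function(map, hmm) {
  sum(!is.na(map)) / nMatchStates(hmm)
}
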