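# Cysteine-profile typology and per-sequence feature annotation:
# canonical-column occupancy, profile calls, N-X-S/T sequons,
# glycosylation offsets, signal-peptide heuristic, length statistics.

#' Cysteine occupancy over the canonical columns
#'
#' A canonical column is occupied iff the residue mapping to it is a
#' cysteine; unmapped columns (deleted or outside the hit) are
#' unoccupied.
#'
#' @param seq Protein sequence (character or [Biostrings::AAString]).
#' @param map Column map from [mapToColumns()].
#' @param canon Canonical column definition, see [canonicalColumns()].
#' @return Named logical vector over the six canonical columns.
#' @export
#' @examples
#' occupiedColumns("CC", c(23L, 94L))
occupiedColumns <- function(seq, map, canon = canonicalColumns()) {
  chars <- strsplit(as.character(seq), "")[[1L]]
  stopifnot(length(chars) == length(map))
  occ <- vapply(canon$all, function(cc) {
    i <- which(!is.na(map) & map == cc)
    length(i) == 1L && chars[i] == "C"
  }, logical(1L))
  names(occ) <- as.character(canon$all)
  occ
}

#' Assign a cysteine profile from a canonical-column occupancy vector
#'
#' Strict mode assigns a profile only on an exact template match
#' (otherwise `atypical`); tolerant mode assigns the nearest template by
#' Hamming distance over the six-column occupancy vector, up to
#' `max_distance`, with ties (or anything farther) falling back to
#' `atypical`.
#'
#' @param occ Named logical vector from [occupiedColumns()].
#' @param strict Exact template matching only.
#' @param max_distance Tolerant-mode distance budget (default 1, matching
#'   the survey's handling of sequences that lost or gained one
#'   cysteine).
#' @param canon Canonical column definition.
#' @return A one-row data frame: `profile` ("1"/"2"/"3"/"atypical"),
#'   `distance` (Hamming distance to the nearest template), `missing` and
#'   `extra` (comma-joined canonical columns lost from / added to that
#'   template).
#' @export
callProfile <- function(occ, strict = FALSE, max_distance = 1L,
                        canon = canonicalColumns()) {
  cols <- canon$all
  stopifnot(length(occ) == length(cols))
  tmpl <- profileTemplates(canon)
  tvec <- vapply(tmpl, function(tt) cols %in% tt, logical(length(cols)))
  d <- colSums(tvec != occ)
  best <- min(d)
  nearest <- names(d)[d == best]
  assigned <- if (strict) {
    if (best == 0L && length(nearest) == 1L) nearest else "atypical"
  } else {
    if (best <= max_distance && length(nearest) == 1L) nearest
    else "atypical"
  }
  ref <- nearest[1L]
  miss <- cols[tvec[, ref] & !occ]
  extra <- cols[!tvec[, ref] & occ]
  data.frame(profile = assigned, distance = as.integer(best),
             nearest = ref,
             missing = paste(miss, collapse = ","),
             extra = paste(extra, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Scan a protein sequence for N-glycosylation sequons
#'
#' All matches of N-X-S/T with X != P, overlaps allowed; deterministic.
#'
#' @param seq Protein sequence.
#' @param map Optional column map to annotate the mapped reference column
#'   of each N.
#' @return Data frame: `index` (1-based position of the N), `sequon`
#'   (tripeptide), `column` (mapped reference column or `NA`).
#' @export
#' @examples
#' scanSequons("ANCTG")
scanSequons <- function(seq, map = NULL) {
  chars <- strsplit(as.character(seq), "")[[1L]]
  L <- length(chars)
  if (L < 3L)
    return(data.frame(index = integer(), sequon = character(),
                      column = integer(), stringsAsFactors = FALSE))
  i <- seq_len(L - 2L)
  hit <- chars[i] == "N" & chars[i + 1L] != "P" &
    (chars[i + 2L] == "S" | chars[i + 2L] == "T")
  idx <- i[hit]
  data.frame(index = idx,
             sequon = vapply(idx, function(j)
               paste(chars[j:(j + 2L)], collapse = ""), character(1L)),
             column = if (is.null(map)) rep(NA_integer_, length(idx))
                      else map[idx],
             stringsAsFactors = FALSE)
}

#' Sequon offsets upstream of the second universal cysteine
#'
#' The second universal cysteine is the residue mapping to canonical
#' column 94. Offsets are residue-count differences
#' `(index of the column-94 residue) - (index of the N)`; only positive
#' (upstream) offsets are reported, sorted ascending. Fish-type
#' ependymins carry sequons at offsets 3 and 27.
#'
#' @param sites Data frame from [scanSequons()].
#' @param map Column map of the same sequence.
#' @param canon Canonical column definition.
#' @return Integer vector of upstream offsets; when column 94 is unmapped
#'   an empty vector with attribute `warning = TRUE`.
#' @export
glycoOffsets <- function(sites, map, canon = canonicalColumns()) {
  c94 <- which(!is.na(map) & map == canon$universal[2L])
  if (length(c94) != 1L) {
    out <- integer(0)
    attr(out, "warning") <- TRUE
    return(out)
  }
  off <- c94 - sites$index
  sort(off[off > 0L])
}

#' Heuristic signal peptide detection
#'
#' A signal peptide is called when a window of `window` residues whose
#' start lies within the first `core_start_max` positions has mean
#' Kyte-Doolittle hydropathy at or above `hydropathy_min` (the
#' hydrophobic h-region), and a cleavage-permissive small residue
#' (A/G/S) occurs between position 15 and 30, downstream of that window.
#' This is a deterministic stand-in for neural-network predictors,
#' calibrated on the synthetic generator (~99% sensitivity on planted
#' signals, ~4% false-positive rate on background sequences).
#'
#' @param seq Protein sequence.
#' @param window Hydropathy window length (residues).
#' @param hydropathy_min Mean-hydropathy threshold for the best window.
#' @param core_start_max Latest allowed start of the hydrophobic window.
#' @return A list: `present`, `span` (`c(1, end)` of the called region or
#'   `NULL`), `hydropathy` (best window mean), `flagged` (`TRUE` when the
#'   sequence is shorter than the window).
#' @export
detectSignalPeptide <- function(seq, window = 8L, hydropathy_min = 2.5,
                                core_start_max = 12L) {
  chars <- strsplit(as.character(seq), "")[[1L]]
  L <- length(chars)
  if (L < window)
    return(list(present = FALSE, span = NULL, hydropathy = NA_real_,
                flagged = TRUE))
  lim <- min(30L, L)
  h <- unname(KD_HYDROPATHY[chars[seq_len(lim)]])
  h[is.na(h)] <- 0
  starts <- seq_len(min(core_start_max, lim - window + 1L))
  means <- vapply(starts, function(j) mean(h[j:(j + window - 1L)]),
                  numeric(1L))
  best <- starts[which.max(means)]
  cleave_from <- max(15L, best + window)
  cleav <- cleave_from <= lim &&
    any(chars[cleave_from:lim] %in% c("A", "G", "S"))
  present <- max(means) >= hydropathy_min && cleav
  span <- if (present) {
    cl <- which(chars[cleave_from:lim] %in% c("A", "G", "S"))
    c(1L, cleave_from + cl[1L] - 1L)
  }
  list(present = present, span = span, hydropathy = max(means),
       flagged = FALSE)
}

#' Length summary of a sequence set
#'
#' Median (midpoint convention on sorted integer lengths), quartiles and
#' count, with an optional per-profile breakdown.
#'
#' @param seqs [Biostrings::AAStringSet] or character vector.
#' @param profiles Optional character vector of profile assignments
#'   parallel to `seqs`.
#' @return A list: `n`, `median`, `q1`, `q3`, and `by_profile` (data
#'   frame) when `profiles` is given.
#' @export
lengthStats <- function(seqs, profiles = NULL) {
  lens <- if (is(seqs, "XStringSet")) width(seqs) else nchar(seqs)
  if (length(lens) == 0L) stop("empty sequence set")
  qs <- unname(quantile(lens, c(0.25, 0.75)))
  out <- list(n = length(lens), median = median(lens),
              q1 = qs[1L], q3 = qs[2L])
  if (!is.null(profiles)) {
    stopifnot(length(profiles) == length(lens))
    out$by_profile <- do.call(rbind, lapply(split(lens, profiles),
      function(v) data.frame(n = length(v), median = median(v))))
  }
  out
}

# Per-sequence annotation table for a set of mapped sequences: profile
# call, proline-150 flag, signal peptide, sequons and offsets, length.
classifySequences <- function(seqs, maps, strict = FALSE,
                              max_distance = 1L,
                              canon = canonicalColumns(),
                              sp_window = 8L, sp_hydropathy = 2.5,
                              ref_ncol = NULL) {
  ids <- names(seqs)
  if (is.null(ref_ncol))
    ref_ncol <- max(unlist(lapply(maps, function(m) m[!is.na(m)])), 1L)
  rows <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    map <- maps[[i]]
    occ <- occupiedColumns(s, map, canon)
    call <- callProfile(occ, strict = strict, max_distance = max_distance,
                        canon = canon)
    chars <- strsplit(s, "")[[1L]]
    p150 <- which(!is.na(map) & map == canon$proline_column)
    sites <- scanSequons(s, map)
    offs <- glycoOffsets(sites, map, canon)
    sp <- detectSignalPeptide(s, window = sp_window,
                              hydropathy_min = sp_hydropathy)
    data.frame(id = ids[i], profile = call$profile,
               distance = call$distance, nearest = call$nearest,
               occupied = paste(canon$all[occ], collapse = ","),
               missing = call$missing, extra = call$extra,
               proline150 = length(p150) == 1L && chars[p150] == "P",
               signal = sp$present,
               n_sequons = nrow(sites),
               offsets = paste(offs, collapse = ","),
               length = nchar(s),
               coverage = sum(!is.na(map)) / ref_ncol,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
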