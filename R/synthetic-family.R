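# Synthetic EPDR-like families with planted, recoverable ground truth.
#
# Non-decoy sequences are built in a 200-column reference space: a clade
# consensus backbone, cysteines planted at the canonical columns of the
# sequence's profile, the conserved proline at column 150, per-site
# substitutions away from the consensus, indels outside a guard band
# around the canonical columns, an N-terminal hydrophobic signal peptide,
# N-X-S/T sequons upstream of the column-94 cysteine, and a divergent
# C-terminal tail that brings the mature length to the sampled target.

#' Configuration for the synthetic family generator
#'
#' @param n_per_profile Sequences generated per cysteine profile (1, 2, 3).
#' @param n_decoys Background-composition decoy sequences.
#' @param length_median Target median mature-protein length (residues).
#' @param length_spread Half inter-quartile width of the length
#'   distribution (residues).
#' @param signal_len Planted signal peptide length (residues).
#' @param n_taxa Number of taxon labels family members are spread across.
#' @param expansion_taxon Optional taxon label receiving an expanded
#'   paralog set (drawn from the profile-1 quota).
#' @param expansion_size Number of paralogs assigned to `expansion_taxon`.
#' @param sequon_rate Expected N-X-S/T sequons planted per family sequence.
#' @param mutation_rate Per-site substitution probability away from the
#'   family consensus (canonical columns are never mutated).
#' @param indel_rate Per-site insertion/deletion probability.
#' @param seed Integer RNG seed; identical configurations are
#'   byte-reproducible.
#' @return A validated list of class `SyntheticConfig`.
#' @export
#' @examples
#' cfg <- syntheticConfig(n_per_profile = 5, n_decoys = 10, seed = 1)
syntheticConfig <- function(n_per_profile = 100L, n_decoys = 1000L,
                            length_median = 213L, length_spread = 15L,
                            signal_len = 18L, n_taxa = 30L,
                            expansion_taxon = NULL, expansion_size = 15L,
                            sequon_rate = 2, mutation_rate = 0.4,
                            indel_rate = 0.02, seed = 1L) {
  cfg <- list(n_per_profile = as.integer(n_per_profile),
              n_decoys = as.integer(n_decoys),
              length_median = as.integer(length_median),
              length_spread = as.integer(length_spread),
              signal_len = as.integer(signal_len),
              n_taxa = as.integer(n_taxa),
              expansion_taxon = expansion_taxon,
              expansion_size = as.integer(expansion_size),
              sequon_rate = sequon_rate,
              mutation_rate = mutation_rate,
              indel_rate = indel_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_per_profile >= 0L, cfg$n_decoys >= 0L, cfg$n_taxa >= 1L,
            cfg$expansion_size >= 0L, cfg$sequon_rate >= 0,
            cfg$mutation_rate >= 0, cfg$mutation_rate <= 1,
            cfg$indel_rate >= 0, cfg$indel_rate <= 1,
            cfg$length_median > cfg$signal_len, cfg$signal_len >= 6L)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# Discretised symmetric length model around the median; the spread is the
# half inter-quartile width (0.6745 sd for a normal).
sampleLengths <- function(n, med, spread) {
  pmax(as.integer(round(rnorm(n, med, spread / 0.6745))),
       as.integer(ceiling(med / 2)))
}

sampleBackground <- function(n) {
  sample(AA_ALPHABET, n, replace = TRUE, prob = BACKGROUND_FREQS)
}

# Consensus backbone of one profile: clade backbone with cysteines planted
# at the profile's canonical columns and the proline at column 150.
plantProfile <- function(profile, canon = canonicalColumns()) {
  clade <- if (profile == 1L) "1" else "2"
  cons <- strsplit(CLADE_CONSENSUS[[clade]], "")[[1L]]
  cons[profileTemplates(canon)[[as.character(profile)]]] <- "C"
  cons[canon$proline_column] <- "P"
  cons
}

# Substitute residues away from `cons` at non-canonical sites.
# Substitutions never introduce cysteine: the family's cysteine
# architecture is fixed (disulfide pairing in a secreted protein), so the
# planted canonical cysteines stay the only ones in the domain core.
mutateConsensus <- function(cons, rate, canon = canonicalColumns()) {
  mutable <- setdiff(seq_along(cons), c(canon$all, canon$proline_column))
  hit <- mutable[runif(length(mutable)) < rate]
  if (length(hit)) {
    noC <- BACKGROUND_FREQS[AA_ALPHABET != "C"]
    pool <- names(noC)
    repl <- sample(pool, length(hit), replace = TRUE, prob = noC / sum(noC))
    while (any(same <- repl == cons[hit]))
      repl[same] <- sample(pool, sum(same), replace = TRUE,
                           prob = noC / sum(noC))
    cons[hit] <- repl
  }
  cons
}

# Columns eligible for indels: outside a +/-5 guard band around canonical
# columns (including the proline), so planted residues are never deleted
# and their local alignment context stays unambiguous.
indelEligible <- function(ncol, canon = canonicalColumns()) {
  guard <- unique(unlist(lapply(c(canon$all, canon$proline_column),
                                function(cc) (cc - 5L):(cc + 5L))))
  setdiff(seq_len(ncol), guard)
}

# Realise a mature domain from a mutated backbone: deletions, insertions,
# and the column map (residue index -> reference column, NA for inserts).
applyIndels <- function(chars, indel_rate, canon = canonicalColumns()) {
  elig <- indelEligible(length(chars), canon)
  del <- elig[runif(length(elig)) < indel_rate / 2]
  ins_ok <- elig[(elig + 1L) %in% elig]
  ins_after <- ins_ok[runif(length(ins_ok)) < indel_rate / 2]
  kept <- setdiff(seq_along(chars), del)
  icnt <- integer(length(chars))
  icnt[ins_after] <- sample(1:3, length(ins_after), replace = TRUE)
  icnt <- icnt[kept]
  idx <- rep(seq_along(kept), times = 1L + icnt)
  first <- !duplicated(idx)
  out <- character(length(idx))
  out[first] <- chars[kept]
  if (any(!first)) out[!first] <- sampleBackground(sum(!first))
  map <- rep(NA_integer_, length(idx))
  map[first] <- kept
  list(res = out, map = map)
}

# Plant N-X-S/T sequons at fixed residue offsets upstream of the
# column-94 cysteine (the fish arrangement uses offsets 3 and 27).
plantSequons <- function(res, map, n_sequons, canon = canonicalColumns()) {
  planted <- integer(0)
  if (n_sequons < 1L) return(list(res = res, positions = planted))
  c94 <- which(!is.na(map) & map == canon$universal[2L])
  if (length(c94) != 1L) return(list(res = res, positions = planted))
  offsets <- c(3L, 27L, 40L, 50L, 60L)[seq_len(min(n_sequons, 5L))]
  avoid <- c(canon$all, canon$proline_column)
  for (off in offsets) {
    pN <- c94 - off
    if (pN < 1L) next
    cols <- map[pN:(pN + 2L)]
    if (any(!is.na(cols) & cols %in% avoid)) next
    res[pN] <- "N"
    if (res[pN + 1L] == "P") res[pN + 1L] <- "A"
    res[pN + 2L] <- "T"
    planted <- c(planted, pN)
  }
  list(res = res, positions = sort(planted))
}

# Hydrophobic signal peptide ending in an A-X-A cleavage motif.
makeSignal <- function(len) {
  core <- sample(names(SIGNAL_CORE_FREQS), len - 3L, replace = TRUE,
                 prob = SIGNAL_CORE_FREQS)
  c(core, "A", sample(c("L", "S"), 1L), "A")
}

emptyTruth <- function() {
  data.frame(id = character(), taxon = character(),
             true_profile = character(), true_clade = character(),
             cys_positions = I(list()), sequon_positions = I(list()),
             signal_start = integer(), signal_end = integer(),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic EPDR-like family with planted ground truth
#'
#' Produces family members for each of the three cysteine profiles plus
#' background decoys. Every non-decoy sequence carries an N-terminal
#' hydrophobic signal peptide, cysteines at exactly the canonical
#' reference columns of its profile, the conserved proline at column 150,
#' planted N-X-S/T sequons, and a divergent C-terminal tail; profile-1
#' sequences belong to clade 1, profile-2/3 sequences to clade 2. When
#' `expansion_taxon` is set, part of the profile-1 quota is generated as a
#' recent paralog cluster assigned to that taxon.
#'
#' @param config A [syntheticConfig()].
#' @return A list with components `sequences` (an
#'   [Biostrings::AAStringSet] named `"id|taxon"`), `truth` (a data frame:
#'   id, taxon, true_profile, true_clade, planted cysteine and sequon
#'   residue indices, signal peptide span), and `maps` (per-sequence
#'   integer vectors mapping residue index to reference column, `NA` where
#'   unmapped; `NULL` for decoys).
#' @export
#' @examples
#' fam <- generateFamily(syntheticConfig(n_per_profile = 3, n_decoys = 2,
#'                                       seed = 7))
#' fam$truth$true_profile
generateFamily <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  canon <- canonicalColumns()
  n <- config$n_per_profile
  if (n == 0L && config$n_decoys == 0L)
    return(list(sequences = AAStringSet(), truth = emptyTruth(),
                maps = list()))

  withSeed(config$seed, {
    taxa <- sprintf("taxon%02d", seq_len(config$n_taxa))
    n_exp <- if (!is.null(config$expansion_taxon))
      min(config$expansion_size, n) else 0L
    ancestor <- if (n_exp > 0L)
      mutateConsensus(plantProfile(1L, canon),
                      0.6 * config$mutation_rate, canon)

    seqs <- character(0)
    truth <- list()
    maps <- list()
    tax_i <- 0L
    i_all <- 0L
    n_seqons <- max(0L, as.integer(round(config$sequon_rate)))

    for (p in 1:3) {
      backbone <- plantProfile(p, canon)
      template <- profileTemplates(canon)[[as.character(p)]]
      for (i in seq_len(n)) {
        i_all <- i_all + 1L
        in_cluster <- p == 1L && i <= n_exp
        base <- if (in_cluster)
          mutateConsensus(ancestor, 0.5 * config$mutation_rate, canon)
        else
          mutateConsensus(backbone, config$mutation_rate, canon)
        mat <- applyIndels(base, config$indel_rate, canon)
        target <- sampleLengths(1L, config$length_median,
                                config$length_spread)
        tail_len <- max(0L, target - length(mat$res))
        res <- c(mat$res, if (tail_len) sampleBackground(tail_len))
        map <- c(mat$map, rep(NA_integer_, tail_len))
        sq <- plantSequons(res, map, n_seqons, canon)
        sig <- makeSignal(config$signal_len)
        full <- c(sig, sq$res)
        s <- config$signal_len
        if (in_cluster) {
          taxon <- config$expansion_taxon
        } else {
          tax_i <- tax_i + 1L
          taxon <- taxa[(tax_i - 1L) %% config$n_taxa + 1L]
        }
        id <- sprintf("seq%04d", i_all)
        seqs[[paste0(id, "|", taxon)]] <- paste(full, collapse = "")
        maps[[id]] <- c(rep(NA_integer_, s), map)
        truth[[i_all]] <- data.frame(
          id = id, taxon = taxon, true_profile = as.character(p),
          true_clade = if (p == 1L) "1" else "2",
          cys_positions = I(list(s + which(!is.na(map) & map %in% template))),
          sequon_positions = I(list(s + sq$positions)),
          signal_start = 1L, signal_end = s,
          stringsAsFactors = FALSE)
      }
    }

    for (i in seq_len(config$n_decoys)) {
      i_all <- i_all + 1L
      len <- sampleLengths(1L, config$length_median, config$length_spread)
      id <- sprintf("decoy%04d", i)
      taxon <- taxa[(i - 1L) %% config$n_taxa + 1L]
      seqs[[paste0(id, "|", taxon)]] <-
        paste(sampleBackground(len), collapse = "")
      truth[[i_all]] <- data.frame(
        id = id, taxon = taxon, true_profile = "decoy", true_clade = "none",
        cys_positions = I(list(integer(0))),
        sequon_positions = I(list(integer(0))),
        signal_start = NA_integer_, signal_end = NA_integer_,
        stringsAsFactors = FALSE)
    }

    list(sequences = AAStringSet(seqs),
         truth = do.call(rbind, truth),
         maps = maps)
  })
}

#' Generate background decoy sequences
#'
#' Sequences drawn i.i.d. from the background amino-acid composition with
#' lengths from the same discretised symmetric model the family generator
#' uses; no scaffold is planted. Negative controls for search calibration.
#'
#' @param n Number of decoys.
#' @param length_stats Numeric `c(median, spread)` of the length model.
#' @param seed Integer RNG seed.
#' @return An [Biostrings::AAStringSet] named `decoy0001`, ...
#' @export
generateDecoys <- function(n, length_stats = c(213, 15), seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0L) return(AAStringSet())
  withSeed(seed, {
    lens <- sampleLengths(n, length_stats[1L], length_stats[2L])
    out <- vapply(lens, function(l) paste(sampleBackground(l), collapse = ""),
                  character(1L))
    names(out) <- sprintf("decoy%04d", seq_len(n))
    AAStringSet(out)
  })
}

#' Generate a synthetic seed alignment in the reference column space
#'
#' Indel-free family members (mature domain only: no signal peptide or
#' tail), so every row has exactly one residue per reference column. Used
#' as the seed alignment for [buildProfile()] in synthetic surveys.
#'
#' @param n_per_profile Rows per cysteine profile.
#' @param mutation_rate Per-site divergence from the consensus backbones.
#' @param seed Integer RNG seed.
#' @return An aligned [Biostrings::AAStringSet] (all rows equal width).
#' @export
syntheticSeedAlignment <- function(n_per_profile = 8L, mutation_rate = 0.4,
                                   seed = 101L) {
  stopifnot(n_per_profile >= 1L)
  canon <- canonicalColumns()
  withSeed(seed, {
    rows <- character(0)
    for (p in 1:3) {
      backbone <- plantProfile(p, canon)
      for (i in seq_len(n_per_profile)) {
        rows[[sprintf("seedp%d_%02d", p, i)]] <-
          paste(mutateConsensus(backbone, mutation_rate, canon),
                collapse = "")
      }
    }
    AAStringSet(rows)
  })
}

#' Write / read a planted-truth table
#'
#' Tab-separated with one row per sequence; coordinate lists are
#' comma-joined. `readTruth()` restores an object identical to the one
#' written.
#'
#' @param truth Truth data frame from [generateFamily()].
#' @param path File path.
#' @return `writeTruth()` returns `path` invisibly; `readTruth()` returns
#'   the truth data frame.
#' @export
writeTruth <- function(truth, path) {
  flat <- data.frame(
    id = truth$id, taxon = truth$taxon,
    true_profile = truth$true_profile, true_clade = truth$true_clade,
    cys_positions = vapply(truth$cys_positions, paste, character(1L),
                           collapse = ","),
    sequon_positions = vapply(truth$sequon_positions, paste, character(1L),
                              collapse = ","),
    signal_start = truth$signal_start, signal_end = truth$signal_end,
    stringsAsFactors = FALSE)
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  flat <- read.delim(path, colClasses = c(
    id = "character", taxon = "character", true_profile = "character",
    true_clade = "character", cys_positions = "character",
    sequon_positions = "character", signal_start = "integer",
    signal_end = "integer"))
  parse_ints <- function(x) lapply(strsplit(x, ","), function(v)
    as.integer(v[nzchar(v)]))
  out <- data.frame(id = flat$id, taxon = flat$taxon,
                    true_profile = flat$true_profile,
                    true_clade = flat$true_clade,
                    cys_positions = I(parse_ints(flat$cys_positions)),
                    sequon_positions = I(parse_ints(flat$sequon_positions)),
                    signal_start = flat$signal_start,
                    signal_end = flat$signal_end,
                    stringsAsFactors = FALSE)
  out
}
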