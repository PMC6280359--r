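# Distance-based phylogeny: pairwise-deletion distances, Saitou-Nei
# neighbor joining with deterministic tie-breaking, nonparametric
# bootstrap supports, two-clade assignment, and lineage-expansion
# detection.

#' Pairwise protein distances under pairwise deletion
#'
#' `p = mismatches / compared columns`, columns where either sequence has
#' a gap excluded per pair. The Poisson correction `d = -ln(1 - p)` (with
#' `p` capped at `cap` as a saturation guard) is the default model.
#'
#' @param aln Aligned [Biostrings::AAStringSet] / character matrix.
#' @param model `"poisson"` or `"p"` (raw p-distance).
#' @param weights Optional integer column weights (bootstrap resampling).
#' @param cap Cap applied to `p` before the Poisson correction.
#' @return Symmetric distance matrix with a `model` attribute and a
#'   `compared` attribute (pairwise site counts).
#' @export
pairwiseDistances <- function(aln, model = c("poisson", "p"),
                              weights = NULL, cap = 0.95) {
  model <- match.arg(model)
  mat <- alignmentMatrix(aln)
  if (nrow(mat) < 3L) stop("need at least 3 sequences")
  pc <- alignmentPairCounts(mat, weights)
  if (any(pc$compared[upper.tri(pc$compared)] == 0))
    stop("sequence pair with zero compared columns")
  p <- 1 - pc$matches / pc$compared
  diag(p) <- 0
  D <- if (model == "poisson") -log(1 - pmin(p, cap)) else p
  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(mat)))
  dimnames(D) <- list(ids, ids)
  attr(D, "model") <- model
  attr(D, "compared") <- pc$compared
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i, j) = (n - 2) d(i, j) - r_i - r_j` is joined, ties broken by the
#' smallest `(i, j)` index pair in the current working order. Branch
#' lengths use the standard formulas; a negative branch length is clamped
#' to zero with the excess transferred to its sibling edge.
#'
#' @param D Symmetric distance matrix (with row/column names) from
#'   [pairwiseDistances()].
#' @return An unrooted [ape::phylo] tree.
#' @export
njTree <- function(D) {
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(D))) stop("non-finite distances")
  labels <- rownames(D)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n))
  Dw <- unname(as.matrix(D))
  repr <- labels
  act <- seq_len(n)
  fmt <- function(x) sprintf("%.10g", x)
  while (length(act) > 3L) {
    na <- length(act)
    sub <- Dw[act, act]
    r <- rowSums(sub)
    Q <- (na - 2) * sub - outer(r, r, "+")
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    ai <- act[i]; aj <- act[j]
    d_ij <- Dw[ai, aj]
    vi <- d_ij / 2 + (r[i] - r[j]) / (2 * (na - 2))
    vj <- d_ij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(vi + vj, 0); vj <- 0 }
    others <- act[-c(i, j)]
    du <- (Dw[ai, others] + Dw[aj, others] - d_ij) / 2
    Dw[ai, others] <- du; Dw[others, ai] <- du
    repr[ai] <- paste0("(", repr[ai], ":", fmt(vi), ",",
                       repr[aj], ":", fmt(vj), ")")
    act <- act[-j]
  }
  a <- act[1L]; b <- act[2L]; c3 <- act[3L]
  va <- max((Dw[a, b] + Dw[a, c3] - Dw[b, c3]) / 2, 0)
  vb <- max((Dw[a, b] + Dw[b, c3] - Dw[a, c3]) / 2, 0)
  vc <- max((Dw[a, c3] + Dw[b, c3] - Dw[a, b]) / 2, 0)
  nwk <- paste0("(", repr[a], ":", fmt(va), ",", repr[b], ":", fmt(vb),
                ",", repr[c3], ":", fmt(vc), ");")
  read.tree(text = nwk)
}

# Descendant tip labels of every internal node.
nodeTipSets <- function(phy) {
  nt <- length(phy$tip.label)
  desc <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- phy$tip.label[i]
  ord <- stats::reorder(phy, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# Canonical key of the bipartition induced by a tip-label side: the side
# not containing the alphabetically first tip, sorted.
splitKey <- function(side, all_tips) {
  ref <- min(all_tips)
  if (ref %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "\r")
}

# Bipartition keys for all internal edges (non-root internal nodes of the
# trifurcating read.tree representation), named by node number.
treeSplits <- function(phy) {
  nt <- length(phy$tip.label)
  desc <- nodeTipSets(phy)
  root <- nt + 1L
  nodes <- setdiff(seq.int(nt + 1L, nt + phy$Nnode), root)
  keys <- vapply(nodes, function(nd) splitKey(desc[[nd]], phy$tip.label),
                 character(1L))
  names(keys) <- nodes
  keys
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Columns are resampled with replacement `reps` times; each replicate
#' distance matrix and NJ tree is computed exactly as for the original
#' alignment, and the support of every original internal edge is the
#' percentage of replicate trees containing its bipartition. Supports are
#' attached as internal node labels.
#'
#' @param aln Aligned [Biostrings::AAStringSet] / character matrix.
#' @param reps Number of bootstrap replicates (the survey default is
#'   100).
#' @param seed Integer RNG seed.
#' @param model Distance model passed to [pairwiseDistances()].
#' @return The NJ tree of the full alignment, with `node.label` holding
#'   per-edge support percentages in `[0, 100]` (empty at the root).
#' @export
bootstrapSupport <- function(aln, reps = 100L, seed = 1L,
                             model = "poisson") {
  stopifnot(reps >= 1L)
  mat <- alignmentMatrix(aln)
  phy <- njTree(pairwiseDistances(mat, model = model))
  keys <- treeSplits(phy)
  counts <- setNames(numeric(length(keys)), names(keys))
  L <- ncol(mat)
  withSeed(seed, {
    for (r in seq_len(reps)) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      trep <- njTree(pairwiseDistances(mat, model = model, weights = w))
      krep <- treeSplits(trep)
      counts <- counts + (keys %in% krep)
    }
  })
  support <- 100 * counts / reps
  nt <- length(phy$tip.label)
  lab <- character(phy$Nnode)
  idx <- as.integer(names(keys)) - nt
  lab[idx] <- sprintf("%g", support)
  phy$node.label <- lab
  attr(phy, "support") <- setNames(support, keys)
  phy
}

#' Assign leaves to the family's two deep clades
#'
#' The internal edge whose bipartition best separates profile-1 leaves
#' from profile-2 leaves (minimum misplacement count) defines the clade
#' split; the side carrying the profile-1 majority is clade 1, and
#' profile-3 / atypical leaves inherit the label of their side. When no
#' edge separates better than the trivial split, every leaf is
#' `"unassigned"` and a warning is raised.
#'
#' @param tree An [ape::phylo] tree.
#' @param profiles Named character vector (tip label -> profile
#'   "1"/"2"/"3"/"atypical").
#' @return Named character vector of clade labels ("1", "2", or
#'   "unassigned") over the tips.
#' @export
assignClades <- function(tree, profiles) {
  tips <- tree$tip.label
  prof <- profiles[tips]
  p1 <- tips[!is.na(prof) & prof == "1"]
  p2 <- tips[!is.na(prof) & prof == "2"]
  if (!length(p1) || !length(p2))
    stop("need at least one profile-1 and one profile-2 leaf as anchors")
  nt <- length(tips)
  desc <- nodeTipSets(tree)
  nodes <- seq.int(nt + 1L, nt + tree$Nnode)[-1L]  # skip root
  if (tree$Nnode < 2L) nodes <- integer(0)
  mis <- function(side) {
    in1 <- sum(p1 %in% side); in2 <- sum(p2 %in% side)
    min((length(p1) - in1) + in2, in1 + (length(p2) - in2))
  }
  trivial <- min(length(p1), length(p2))
  best <- trivial; best_side <- NULL; best_size <- Inf
  # a 3-leaf tree has no internal edge; its terminal edges are the only
  # bipartitions available
  sides <- lapply(nodes, function(nd) desc[[nd]])
  if (nt == 3L) sides <- c(sides, as.list(tips))
  for (side in sides) {
    m <- mis(side)
    if (m >= trivial) next
    # orient to the clade-1 (profile-1 majority) side; ties between
    # equally separating edges prefer the smallest clade-1 side, so
    # non-anchor (profile-3 / atypical) leaves are not pulled into clade 1
    side1 <- if (sum(p1 %in% side) / length(p1) >= 0.5) side
             else setdiff(tips, side)
    if (is.null(best_side) || m < best ||
        (m == best && length(side1) < best_size)) {
      best <- m; best_side <- side; best_size <- length(side1)
    }
  }
  if (is.null(best_side)) {
    warning("no internal edge separates the profile anchors; all leaves unassigned")
    return(setNames(rep("unassigned", nt), tips))
  }
  in_side <- tips %in% best_side
  side_p1 <- sum(p1 %in% best_side) / length(p1)
  clade1_in_side <- side_p1 >= 0.5
  lab <- ifelse(in_side == clade1_in_side, "1", "2")
  setNames(lab, tips)
}

#' Detect lineage-specific gene-family expansions
#'
#' A species is flagged as expanded when its family-member count reaches
#' `count_threshold` (the survey uses 15 or more). When a tree is given,
#' maximal monophyletic same-taxon clades of at least `clade_min` leaves
#' are reported as evidence of taxon-specific duplication.
#'
#' @param taxa Named character vector (sequence id -> taxon).
#' @param tree Optional [ape::phylo] with tip labels matching the ids.
#' @param count_threshold Per-species count at or above which a species
#'   is flagged.
#' @param clade_min Minimum size of a reported same-taxon clade.
#' @return A list: `species` (data frame taxon/count/expanded), `clades`
#'   (data frame taxon/size for maximal same-taxon clades), and
#'   `clade_members` (list of tip-label vectors).
#' @export
detectExpansions <- function(taxa, tree = NULL, count_threshold = 15L,
                             clade_min = 2L) {
  counts <- table(taxa)
  species <- data.frame(taxon = names(counts),
                        count = as.integer(counts),
                        expanded = as.integer(counts) >= count_threshold,
                        stringsAsFactors = FALSE)
  species <- species[order(-species$count, species$taxon), , drop = FALSE]
  rownames(species) <- NULL
  clades <- data.frame(taxon = character(), size = integer(),
                       stringsAsFactors = FALSE)
  members <- list()
  if (!is.null(tree)) {
    tips <- tree$tip.label
    ttax <- taxa[tips]
    nt <- length(tips)
    desc <- nodeTipSets(tree)
    cand <- list()
    for (nd in seq.int(nt + 1L, nt + tree$Nnode)) {
      for (side in list(desc[[nd]], setdiff(tips, desc[[nd]]))) {
        if (length(side) < clade_min || length(side) >= nt) next
        tx <- unique(ttax[side])
        if (length(tx) == 1L && !is.na(tx))
          cand[[length(cand) + 1L]] <- list(taxon = tx, tips = side)
      }
    }
    if (length(cand)) {
      keep <- rep(TRUE, length(cand))
      for (i in seq_along(cand)) for (j in seq_along(cand)) {
        if (i != j && keep[i] &&
            length(cand[[i]]$tips) < length(cand[[j]]$tips) &&
            all(cand[[i]]$tips %in% cand[[j]]$tips))
          keep[i] <- FALSE
      }
      # drop duplicate tip sets (both sides of adjacent edges can agree)
      seen <- character(0)
      for (i in which(keep)) {
        key <- paste(sort(cand[[i]]$tips), collapse = "\r")
        if (key %in% seen) { keep[i] <- FALSE; next }
        seen <- c(seen, key)
      }
      cand <- cand[keep]
      if (length(cand)) {
        clades <- data.frame(
          taxon = vapply(cand, `[[`, character(1L), "taxon"),
          size = vapply(cand, function(x) length(x$tips), integer(1L)),
          stringsAsFactors = FALSE)
        members <- lapply(cand, `[[`, "tips")
        ord <- order(-clades$size, clades$taxon)
        clades <- clades[ord, , drop = FALSE]
        rownames(clades) <- NULL
        members <- members[ord]
      }
    }
  }
  list(species = species, clades = clades, clade_members = members)
}
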