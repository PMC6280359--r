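# Distances, neighbor joining, bootstrap support, clade assignment and
# expansion detection.

test_that("pairwise distances match closed forms and a brute-force loop", {
  a <- paste(rep("A", 100L), collapse = "")
  b <- paste(c(rep("A", 95L), rep("C", 5L)), collapse = "")
  c3 <- paste(c(rep("V", 50L), rep("A", 50L)), collapse = "")
  aln <- c(x = a, y = b, z = c3)
  P <- pairwiseDistances(aln, model = "p")
  expect_equal(P["x", "x"], 0)
  expect_equal(P["x", "y"], 0.05, tolerance = 1e-12)
  D <- pairwiseDistances(aln, model = "poisson")
  expect_equal(D["x", "y"], -log(0.95), tolerance = 1e-12)
  expect_true(isSymmetric(unclass(D)))
  # brute-force double loop over random sequences with gaps
  set.seed(6)
  rows <- vapply(1:10, function(i)
    paste(sample(c(AA20, "-"), 60L, replace = TRUE), collapse = ""),
    character(1L))
  names(rows) <- sprintf("s%02d", 1:10)
  Dp <- pairwiseDistances(rows, model = "p")
  mats <- strsplit(rows, "")
  for (i in 1:9) for (j in (i + 1):10) {
    ri <- mats[[i]]; rj <- mats[[j]]
    comp <- ri != "-" & rj != "-"
    expect_equal(unname(Dp[i, j]), sum(ri[comp] != rj[comp]) / sum(comp),
                 tolerance = 1e-12)
  }
  # a pair sharing no columns is an error
  expect_error(pairwiseDistances(c(a = "A-", b = "-A", c = "AA")), "zero")
})

test_that("three-taxon neighbor joining reproduces the three-point formulas", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3L, 3L,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- njTree(D)
  bl <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2L]])
  expect_equal(unname(bl["a"]), (5 + 9 - 10) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["b"]), (5 + 10 - 9) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["c"]), (9 + 10 - 5) / 2, tolerance = 1e-9)
  expect_error(njTree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(6:10, 1L)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    D <- cophenetic(ref)
    est <- njTree(D[sort(rownames(D)), sort(rownames(D))])
    expect_equal(unname(phangorn::RF.dist(ape::unroot(ref), est)), 0)
  }
})

test_that("NJ agrees topologically with an independent implementation", {
  set.seed(21)
  rows <- vapply(1:8, function(i)
    paste(sample(AA20, 80L, replace = TRUE), collapse = ""), character(1L))
  names(rows) <- sprintf("s%d", 1:8)
  D <- pairwiseDistances(rows, model = "p")
  mine <- njTree(D)
  ref <- ape::nj(as.dist(D))
  expect_equal(unname(phangorn::RF.dist(mine, ref)), 0)
})

test_that("serialization round trip preserves the topology", {
  set.seed(3)
  rows <- vapply(1:6, function(i)
    paste(sample(AA20, 60L, replace = TRUE), collapse = ""), character(1L))
  names(rows) <- sprintf("s%d", 1:6)
  tree <- njTree(pairwiseDistances(rows))
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tree, path)
  back <- ape::read.tree(path)
  expect_equal(unname(phangorn::RF.dist(tree, back)), 0)
})

test_that("bootstrap supports behave at the degenerate extremes", {
  # one replicate: supports can only be 0 or 100
  set.seed(14)
  rows <- vapply(1:6, function(i)
    paste(sample(AA20, 40L, replace = TRUE), collapse = ""), character(1L))
  names(rows) <- sprintf("s%d", 1:6)
  t1 <- bootstrapSupport(rows, reps = 1L, seed = 3L)
  expect_true(all(attr(t1, "support") %in% c(0, 100)))
  # an alignment whose columns are all copies of one pattern is
  # invariant under resampling: every bipartition at 100
  pat <- c("A", "C", "D", "E", "F", "G")
  dup <- vapply(seq_along(pat), function(i)
    paste(rep(pat[i], 30L), collapse = ""), character(1L))
  names(dup) <- sprintf("s%d", 1:6)
  td <- bootstrapSupport(dup, reps = 20L, seed = 5L)
  expect_true(all(attr(td, "support") == 100))
  # reproducible under a fixed seed, supports within [0, 100]
  t2 <- bootstrapSupport(rows, reps = 10L, seed = 9L)
  t3 <- bootstrapSupport(rows, reps = 10L, seed = 9L)
  expect_identical(attr(t2, "support"), attr(t3, "support"))
  expect_true(all(attr(t2, "support") >= 0 & attr(t2, "support") <= 100))
})

test_that("planted clades are recovered and labelled through the tree", {
  fam <- smallBundle()
  tru <- fam$truth
  famrows <- tru$true_profile != "decoy"
  seqs <- fam$sequences[famrows]
  names(seqs) <- tru$id[famrows]
  aln <- impliedAlignment(seqs, fam$maps[names(seqs)], ncol = 200L)
  tree <- bootstrapSupport(aln, reps = 25L, seed = 7L)
  p1 <- tru$id[famrows & tru$true_profile == "1"]
  key <- epdrsurvey:::splitKey(p1, tree$tip.label)
  sup <- attr(tree, "support")
  expect_true(key %in% names(sup))
  expect_gte(unname(sup[key]), 90)
  profs <- setNames(tru$true_profile[famrows], tru$id[famrows])
  clades <- assignClades(tree, profs)
  expect_true(all(clades[p1] == "1"))
  expect_true(all(clades[setdiff(names(clades), p1)] == "2"))
  # leaf-order permutation invariance
  perm <- sample(length(tree$tip.label))
  clades2 <- assignClades(tree, profs[perm])
  expect_identical(clades2[names(clades)], clades)
})

test_that("clade assignment degrades gracefully", {
  # 3-leaf tree with single-leaf anchor groups
  t3 <- ape::read.tree(text = "(a:1,b:1,c:1);")
  lab <- assignClades(t3, c(a = "1", b = "2", c = "2"))
  expect_identical(unname(lab["a"]), "1")
  expect_identical(unname(lab["b"]), "2")
  # profiles interleaved so that every edge mixes the anchors equally:
  # warning path, all unassigned
  nwk <- ape::read.tree(text = paste0(
    "((a1:1,b1:1):1,(a2:1,b2:1):1,((a3:1,b3:1):1,(a4:1,b4:1):1):1);"))
  profs <- setNames(rep(c("1", "2"), 4L),
                    c("a1", "b1", "a2", "b2", "a3", "b3", "a4", "b4"))
  expect_warning(lab2 <- assignClades(nwk, profs), "unassigned")
  expect_true(all(lab2 == "unassigned"))
  expect_error(assignClades(t3, c(a = "1", b = "1", c = "1")), "anchor")
})

test_that("expansions are flagged at the count threshold, strictly", {
  taxa <- setNames(c(rep("spA", 14L), rep("spB", 15L), "spC"),
                   sprintf("g%02d", 1:30))
  rep1 <- detectExpansions(taxa, tree = NULL, count_threshold = 15L)
  expect_false(rep1$species$expanded[rep1$species$taxon == "spA"])
  expect_true(rep1$species$expanded[rep1$species$taxon == "spB"])
})

test_that("maximal same-taxon clades are read off the tree", {
  nwk <- "(((a1:1,a2:1):1,(a3:1,a4:1):1):1,((b1:1,b2:1):1,c1:1):1,d1:1);"
  tree <- ape::read.tree(text = nwk)
  taxa <- setNames(c("A", "A", "A", "A", "B", "B", "C", "D"),
                   c("a1", "a2", "a3", "a4", "b1", "b2", "c1", "d1"))
  rep2 <- detectExpansions(taxa, tree, count_threshold = 4L,
                           clade_min = 2L)
  expect_identical(rep2$clades$taxon, c("A", "B"))
  expect_identical(rep2$clades$size, c(4L, 2L))
  # every leaf a distinct taxon -> no clades
  solo <- setNames(LETTERS[1:8], tree$tip.label)
  expect_identical(nrow(detectExpansions(solo, tree)$clades), 0L)
})

test_that("a planted expansion taxon forms a large monophyletic clade", {
  cfg <- syntheticConfig(n_per_profile = 20L, n_decoys = 0L, seed = 7L,
                         expansion_taxon = "taxonE", expansion_size = 17L)
  fam <- generateFamily(cfg)
  tru <- fam$truth
  seqs <- fam$sequences
  names(seqs) <- tru$id
  aln <- impliedAlignment(seqs, fam$maps[tru$id], ncol = 200L)
  tree <- njTree(pairwiseDistances(aln))
  taxa <- setNames(tru$taxon, tru$id)
  rep3 <- detectExpansions(taxa, tree, count_threshold = 15L)
  expect_true(rep3$species$expanded[rep3$species$taxon == "taxonE"])
  eclades <- rep3$clades[rep3$clades$taxon == "taxonE", ]
  expect_gte(max(eclades$size), 10L)
})
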