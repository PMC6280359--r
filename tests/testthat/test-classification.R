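# Cysteine-profile typology, sequon scanning, glycosylation offsets,
# signal-peptide heuristic and length statistics.

test_that("canonical-column occupancy requires a cysteine at the mapped residue", {
  # C at columns 23, 94, 148, 186 only (profile-1 pattern)
  seq <- "CCCC"
  occ <- occupiedColumns(seq, c(23L, 94L, 148L, 186L))
  expect_identical(unname(occ), c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  # serine at column 94 leaves it unoccupied
  occ2 <- occupiedColumns("CSC", c(23L, 94L, 186L))
  expect_false(occ2[["94"]])
  # decoy with no mapped cysteines
  occ3 <- occupiedColumns("AAAA", rep(NA_integer_, 4L))
  expect_true(all(!occ3))
})

test_that("profile calls agree with a brute-force template-distance table", {
  canon <- canonicalColumns()
  tmpl <- profileTemplates()
  tvecs <- lapply(tmpl, function(tt) canon$all %in% tt)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 6L))
  for (i in seq_len(nrow(grid))) {
    occ <- unlist(grid[i, ])
    names(occ) <- as.character(canon$all)
    d <- vapply(tvecs, function(tv) sum(tv != occ), integer(1L))
    best <- min(d); nearest <- names(d)[d == best]
    strict_exp <- if (best == 0L) nearest else "atypical"
    tol_exp <- if (best <= 1L && length(nearest) == 1L) nearest
               else "atypical"
    cs <- callProfile(occ, strict = TRUE)
    ct <- callProfile(occ, strict = FALSE, max_distance = 1L)
    expect_identical(cs$profile, strict_exp)
    expect_identical(ct$profile, tol_exp)
    expect_identical(cs$distance, best)
  }
})

test_that("the published template patterns are called exactly", {
  canon <- canonicalColumns()
  mkocc <- function(cols) {
    occ <- canon$all %in% cols
    names(occ) <- as.character(canon$all)
    occ
  }
  expect_identical(callProfile(mkocc(c(23, 24, 94, 107, 148, 186)))$profile, "2")
  expect_identical(callProfile(mkocc(c(23, 94, 107, 186)))$profile, "3")
  expect_identical(callProfile(mkocc(c(23, 94, 148, 186)))$profile, "1")
  # lost cysteine 23: tolerant rescues profile 1, strict does not
  lost <- mkocc(c(94, 148, 186))
  expect_identical(callProfile(lost, strict = FALSE)$profile, "1")
  expect_identical(callProfile(lost, strict = FALSE)$distance, 1L)
  expect_identical(callProfile(lost, strict = TRUE)$profile, "atypical")
})

test_that("profile templates carry the expected number of extra cysteines", {
  tmpl <- profileTemplates()
  universal <- canonicalColumns()$universal
  extras <- vapply(tmpl, function(tt) length(setdiff(tt, universal)),
                   integer(1L))
  expect_identical(unname(extras), c(1L, 3L, 1L))
})

test_that("sequon scanning matches the exhaustive window oracle", {
  expect_identical(nrow(scanSequons("NPS")), 0L)
  hit <- scanSequons("ANCTG")
  expect_identical(hit$index, 2L)
  expect_identical(hit$sequon, "NCT")
  set.seed(12)
  big <- paste(sample(AA20, 10000L, replace = TRUE), collapse = "")
  expect_identical(scanSequons(big)$index, oracleSequons(big))
  # direction invariance: scanning the same content must give the same
  # sites wherever they sit
  expect_identical(scanSequons(paste0("AAA", "NCT"))$index, 4L)
})

test_that("glycosylation offsets are counted upstream of the column-94 cysteine", {
  map <- seq_len(100L)
  sites <- data.frame(index = c(91L, 97L, 67L), sequon = "NXT",
                      column = NA_integer_)
  off <- glycoOffsets(sites, map)
  expect_identical(off, c(3L, 27L))   # downstream N excluded, sorted
  nomap <- glycoOffsets(sites, rep(NA_integer_, 100L))
  expect_length(nomap, 0L)
  expect_true(attr(nomap, "warning"))
})

test_that("planted sequons are recovered at offsets 3 and 27", {
  fam <- smallBundle()
  tru <- fam$truth
  ids <- tru$id[tru$true_profile == "1"]
  seqs <- fam$sequences
  names(seqs) <- epdrsurvey:::parseTaxa(names(seqs))$id
  for (id in ids[1:5]) {
    map <- fam$maps[[id]]
    sites <- scanSequons(as.character(seqs[[id]]), map)
    off <- glycoOffsets(sites, map)
    expect_true(all(c(3L, 27L) %in% off))
  }
})

test_that("signal peptide heuristic honours hydropathy and cleavage rules", {
  body <- paste(rep("D", 180L), collapse = "")
  present <- detectSignalPeptide(paste0(paste(rep("L", 20L), collapse = ""),
                                        "ALA", body))
  expect_true(present$present)
  expect_identical(present$span[1L], 1L)
  absent <- detectSignalPeptide(paste0(paste(rep("D", 25L), collapse = ""),
                                       body))
  expect_false(absent$present)
  short <- detectSignalPeptide("LLL")
  expect_false(short$present)
  expect_true(short$flagged)
})

test_that("signal peptides are recovered on planted data and rare in decoys", {
  fam <- generateFamily(syntheticConfig(n_per_profile = 50L,
                                        n_decoys = 200L, seed = 7L))
  isdec <- fam$truth$true_profile == "decoy"
  pres <- vapply(as.character(fam$sequences),
                 function(s) detectSignalPeptide(s)$present, logical(1L))
  expect_gte(mean(pres[!isdec]), 0.95)
  expect_lte(mean(pres[isdec]), 0.10)
})

test_that("length statistics use the midpoint median convention", {
  expect_identical(lengthStats(c("A", "AA", "AAA"))$median, 2L)
  expect_identical(lengthStats(c("A", "AA", "AAA", "AAAA"))$median, 2.5)
  expect_error(lengthStats(character(0)), "empty")
  st <- lengthStats(c("A", "AA", "AAA", "AAAA"),
                    profiles = c("1", "1", "2", "2"))
  expect_identical(st$by_profile["1", "median"], 1.5)
  expect_identical(st$by_profile["2", "median"], 3.5)
})
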