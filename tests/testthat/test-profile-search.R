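# Profile construction, forward/Viterbi scoring against brute-force
# enumeration, Gumbel calibration, and database search behaviour.

test_that("ungapped identical rows give one match state per column", {
  aln <- Biostrings::AAStringSet(c(a = "ACDEF", b = "ACDEF"))
  hmm <- buildProfile(aln)
  expect_identical(nMatchStates(hmm), 5L)
  argmax <- colnames(hmm@match)[apply(hmm@match, 1L, which.max)]
  expect_identical(argmax, c("A", "C", "D", "E", "F"))
  expect_identical(columnMap(hmm), 1:5)
})

test_that("occupancy threshold is inclusive at the boundary", {
  aln <- c(a = "A-C", b = "AAC", c = "A-C", d = "AAC")  # col 2: 50% gaps
  hmm <- buildProfile(aln, match_occupancy_threshold = 0.5)
  expect_identical(nMatchStates(hmm), 3L)
  sparse <- c(a = "A-", b = "-A")  # both columns at 50% occupancy
  expect_error(buildProfile(sparse, match_occupancy_threshold = 0.9),
               "degenerate")
})

test_that("emissions equal the hand-computed pseudocount formula", {
  rows <- c(r1 = "ACD", r2 = "ACD", r3 = "AVD", r4 = "GC-", r5 = "AC-")
  pc <- 1.3
  hmm <- buildProfile(rows, pseudocount = pc)
  # hand computation from raw counts, independently of the builder
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  res <- mat[mat != "-"]
  q <- (as.numeric(table(factor(res, levels = AA20))) + 1) /
    (length(res) + 20)
  for (j in 1:3) {
    col <- mat[, j]; col <- col[col != "-"]
    cnt <- as.numeric(table(factor(col, levels = AA20)))
    expect_equal(unname(hmm@match[j, ]),
                 (cnt + pc * q) / (length(col) + pc), tolerance = 1e-12)
  }
})

test_that("single-state score matches the closed form from the model slots", {
  hmm <- buildProfile(c(a = "C", b = "C"))
  r <- scoreSequence(hmm, "C")
  odds <- hmm@begin[["BM"]] * hmm@match[1L, "C"] / hmm@q[["C"]] +
    2 * hmm@begin[["BD"]]  # all-flank paths with entry before/after the C
  expect_equal(r$bitscore, unname(log2(odds)), tolerance = 1e-12)
})

test_that("a background-emitting profile scores all same-length sequences equally", {
  hmm <- nullToyProfile(4L)
  s1 <- scoreSequence(hmm, "ACDEFG", do_path = FALSE)$bitscore
  s2 <- scoreSequence(hmm, "WYWYWY", do_path = FALSE)$bitscore
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("forward and Viterbi equal brute-force path enumeration", {
  set.seed(4)
  for (rep in 1:30) {
    m <- sample(1:4, 1L)
    L <- sample(1:4, 1L)
    hmm <- randomToyProfile(m)
    codes <- sample(20L, L, replace = TRUE)
    seq <- paste(AA20[codes], collapse = "")
    r <- scoreSequence(hmm, seq)
    expect_equal(r$bitscore, log2(bruteOdds(hmm, codes, "sum")),
                 tolerance = 1e-9)
    expect_equal(r$viterbi_bits, log2(bruteOdds(hmm, codes, "max")),
                 tolerance = 1e-9)
    # sum over paths can never be smaller than the best path
    expect_gte(r$bitscore, r$viterbi_bits - 1e-12)
  }
})

test_that("forward probabilities over all tripeptides sum to the model's length-3 mass", {
  set.seed(9)
  hmm <- randomToyProfile(3L)
  grid <- expand.grid(a = 1:20, b = 1:20, c = 1:20)
  total <- 0
  lp <- 0
  for (i in seq_len(nrow(grid))) {
    codes <- as.integer(grid[i, ])
    seq <- paste(AA20[codes], collapse = "")
    odds <- 2^scoreSequence(hmm, seq, do_path = FALSE)$bitscore
    total <- total + odds * prod(hmm@q[codes])
  }
  expect_equal(total, bruteTotalLengthProb(hmm, 3L), tolerance = 1e-9)
})

test_that("appending consensus residues never hurts the Viterbi path", {
  set.seed(2)
  hmm <- randomToyProfile(4L)
  cons <- colnames(hmm@match)[apply(hmm@match, 1L, which.max)]
  prev <- -Inf
  for (k in 1:4) {
    v <- scoreSequence(hmm, paste(cons[1:k], collapse = ""))$viterbi_bits
    expect_gte(v, prev - 1e-9)
    prev <- v
  }
})

test_that("Gumbel calibration recovers known parameters", {
  set.seed(31)
  lambda <- 0.7; mu <- 2
  x <- mu - log(-log(runif(5000))) / lambda
  fit <- epdrsurvey:::fitGumbel(x)
  expect_lt(abs(fit[["lambda"]] - lambda) / lambda, 0.05)
  expect_lt(abs(fit[["mu"]] - mu), 0.1)
  expect_error(epdrsurvey:::fitGumbel(rep(1, 200)), "degenerate")
})

test_that("calibration is reproducible and enforces its sample-size floor", {
  hmm <- buildProfile(syntheticSeedAlignment(n_per_profile = 3L))
  expect_error(calibrateEvalue(hmm, n_random = 99L), "100")
  c1 <- calibrateEvalue(hmm, n_random = 120L, seed = 5L, N = 50)
  c2 <- calibrateEvalue(hmm, n_random = 120L, seed = 5L, N = 50)
  expect_identical(c(c1@lambda, c1@mu), c(c2@lambda, c2@mu))
  # E-values are monotone decreasing in the bit score and clamped
  ev <- evalueOf(c1, c(-100, 0, 50, 1000))
  expect_true(all(diff(ev) <= 0))
  expect_true(all(ev >= 0 & ev <= c1@N))
})

test_that("search separates planted family members from decoys at 1e-5", {
  fam <- smallBundle()
  seqs <- fam$sequences
  names(seqs) <- epdrsurvey:::parseTaxa(names(seqs))$id
  hmm <- buildProfile(syntheticSeedAlignment())
  cal <- calibrateEvalue(hmm, n_random = 150L, seed = 2L, N = length(seqs))
  hits <- searchDomains(hmm, seqs, cal)
  is_fam <- fam$truth$true_profile[match(hits$id, fam$truth$id)] != "decoy"
  expect_true(all(hits$pass[is_fam]))
  expect_gte(mean(!hits$pass[!is_fam]), 0.99)
  # sorted by E-value, family first
  expect_true(!is.unsorted(hits$evalue))
  # degenerate cutoff accepts everything
  all_in <- searchDomains(hmm, seqs, cal, cutoff = Inf)
  expect_true(all(all_in$pass))
  # empty database
  expect_identical(nrow(searchDomains(hmm, Biostrings::AAStringSet(), cal)), 0L)
})

test_that("profiles survive a JSON serialization round trip", {
  hmm <- buildProfile(syntheticSeedAlignment(n_per_profile = 2L))
  path <- tempfile(fileext = ".json")
  writeProfile(hmm, path)
  back <- readProfile(path)
  expect_equal(back@match, hmm@match, tolerance = 1e-12)
  expect_equal(back@transitions, hmm@transitions, tolerance = 1e-12)
  expect_identical(back@columnMap, hmm@columnMap)
  s <- "MKLVFLALC"
  expect_equal(scoreSequence(back, s)$bitscore,
               scoreSequence(hmm, s)$bitscore, tolerance = 1e-10)
})
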