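# End-to-end survey orchestration: planted-truth recovery at small
# scale, determinism, artifact writing, classification-only mode and
# group summaries.

surveyFixture <- function() {
  if (is.null(.fixture_env$survey)) {
    fam <- smallBundle()
    cfg <- surveyConfig(proteomes = fam$sequences,
                        seed_aln = syntheticSeedAlignment(),
                        n_random = 150L, bootstrap_reps = 10L, seed = 5L)
    .fixture_env$survey <- list(fam = fam, cfg = cfg,
                                report = runSurvey(cfg))
  }
  .fixture_env$survey
}

test_that("the survey recovers the planted family and its labels", {
  fx <- surveyFixture()
  rep <- fx$report
  tru <- fx$fam$truth
  famids <- tru$id[tru$true_profile != "decoy"]
  expect_identical(sort(rep$calls$id), sort(famids))
  m <- match(rep$calls$id, tru$id)
  expect_identical(rep$calls$profile, tru$true_profile[m])
  expect_identical(rep$calls$taxon, tru$taxon[m])
  expect_identical(unname(rep$calls$clade), tru$true_clade[m])
  # species counts reconcile with the generator truth
  cnt <- table(tru$taxon[tru$true_profile != "decoy"])
  m2 <- match(rep$species$taxon, names(cnt))
  expect_identical(rep$species$count, as.integer(cnt)[m2])
  # no sequence in the report failed the E-value cutoff
  ev <- rep$hits$evalue[match(rep$calls$id, rep$hits$id)]
  expect_true(all(ev <= fx$cfg$evalue_cutoff))
  # counts reconcile at stage boundaries
  expect_identical(rep$meta$n_accepted, nrow(rep$calls))
  expect_identical(rep$meta$n_input, length(fx$fam$sequences))
})

test_that("rerunning an identical configuration is byte-reproducible", {
  fx <- surveyFixture()
  d1 <- file.path(tempdir(), "survey_rep1")
  d2 <- file.path(tempdir(), "survey_rep2")
  cfg1 <- fx$cfg; cfg1$out_dir <- d1
  cfg2 <- fx$cfg; cfg2$out_dir <- d2
  runSurvey(cfg1); runSurvey(cfg2)
  for (f in c("report.json", "calls.tsv", "tree.nwk", "hits.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_true(file.exists(file.path(d1, "accepted.fasta")))
  expect_true(file.exists(file.path(d1, "conservation_profile2.tsv")))
})

test_that("an empty proteome yields an empty report with a warning", {
  cfg <- surveyConfig(proteomes = Biostrings::AAStringSet(),
                      seed_aln = syntheticSeedAlignment())
  expect_warning(rep <- runSurvey(cfg), "empty")
  expect_null(rep$calls)
  expect_identical(rep$meta$n_input, 0L)
})

test_that("classification-only mode reproduces the pipeline's calls", {
  fx <- surveyFixture()
  tru <- fx$fam$truth
  famnames <- names(fx$fam$sequences)[tru$true_profile != "decoy"]
  co <- classificationOnlyMode(fx$fam$sequences[famnames],
                               syntheticSeedAlignment(), fx$cfg)
  cols <- c("id", "profile", "distance", "occupied", "proline150",
            "signal", "n_sequons", "offsets")
  a <- fx$report$calls[order(fx$report$calls$id), cols]
  b <- co$calls[order(co$calls$id), cols]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  # single sequence: calls still emitted, tree skipped with a warning
  expect_warning(
    solo <- classificationOnlyMode(fx$fam$sequences[famnames[1L]],
                                   syntheticSeedAlignment(), fx$cfg),
    "tree")
  expect_identical(nrow(solo$calls), 1L)
  expect_null(solo$tree)
})

test_that("group summaries cross-tabulate profiles against clades", {
  fx <- surveyFixture()
  s <- summarizeByGroup(fx$report)
  expect_identical(sum(s$by_profile$n), nrow(fx$report$calls))
  xt <- s$profile_by_clade
  expect_identical(unname(xt["1", "1"]), 15L)
  expect_identical(unname(xt["2", "2"]) + unname(xt["3", "2"]), 30L)
  expect_identical(sum(xt[, "2"]), 30L)
  expect_identical(unname(xt["1", "2"]), 0L)
  expect_true(all(rowSums(s$presence) >= 1L))
  # empty report yields empty tables
  empty <- summarizeByGroup(list(calls = NULL))
  expect_identical(nrow(empty$by_profile), 0L)
})

test_that("taxon parsing sniffs both header styles with a mapping fallback", {
  p <- epdrsurvey:::parseTaxa(c("seq1|taxonA", "Genus species|seq2", "bare1"))
  expect_identical(p$id, c("seq1", "seq2", "bare1"))
  expect_identical(p$taxon, c("taxonA", "Genus species", "unknown"))
  tm <- data.frame(id = "bare1", taxon = "Mapped sp.")
  p2 <- epdrsurvey:::parseTaxa(c("bare1", "seq1|taxonA"), tm)
  expect_identical(p2$taxon, c("Mapped sp.", "taxonA"))
})
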