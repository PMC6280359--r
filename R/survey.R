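# Survey orchestration: search -> map -> trim/dedup -> classify ->
# conservation -> phylogeny -> report, with seed control and versioned
# artifacts.

#' Survey configuration
#'
#' @param proteomes FASTA path(s), or an [Biostrings::AAStringSet].
#' @param seed_aln Aligned-FASTA path or [Biostrings::AAStringSet] seed
#'   alignment defining the reference column space.
#' @param out_dir Output directory for artifacts (`NULL` writes nothing).
#' @param evalue_cutoff Search acceptance E-value (default 1e-5).
#' @param dedup_threshold Pairwise identity at or above which sequences
#'   are redundant (default 0.97).
#' @param coverage_threshold Minimum fraction of match states a hit must
#'   cover (default 0.6).
#' @param trim_threshold Occupancy threshold for alignment trimming.
#' @param conservation_threshold Frequency for "conserved" column calls.
#' @param occupancy_threshold Match-state occupancy for profile building.
#' @param pseudocount Profile smoothing weight.
#' @param n_random Calibration sample size.
#' @param distance_model `"poisson"` or `"p"`.
#' @param bootstrap_reps Bootstrap replicates (default 100).
#' @param expansion_threshold Per-species count flagged as an expansion
#'   (default 15).
#' @param clade_min Minimum reported same-taxon clade size.
#' @param strict_calls Strict (exact-template) profile calling.
#' @param max_call_distance Tolerant-mode distance budget.
#' @param canonical Canonical column definition (overridable for other
#'   families), see [canonicalColumns()].
#' @param taxon_map Optional data frame / TSV path with columns `id`,
#'   `taxon` used when FASTA headers carry no taxon.
#' @param seed Integer seed controlling calibration and bootstrap.
#' @return A list of class `SurveyConfig`.
#' @export
surveyConfig <- function(proteomes = NULL, seed_aln = NULL, out_dir = NULL,
                         evalue_cutoff = 1e-5, dedup_threshold = 0.97,
                         coverage_threshold = 0.6, trim_threshold = 0.5,
                         conservation_threshold = 0.9,
                         occupancy_threshold = 0.5, pseudocount = 1,
                         n_random = 1000L,
                         distance_model = "poisson",
                         bootstrap_reps = 100L,
                         expansion_threshold = 15L, clade_min = 2L,
                         strict_calls = FALSE, max_call_distance = 1L,
                         canonical = canonicalColumns(),
                         taxon_map = NULL, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$evalue_cutoff > 0, cfg$dedup_threshold > 0,
            cfg$dedup_threshold <= 1, cfg$coverage_threshold >= 0,
            cfg$coverage_threshold <= 1, cfg$bootstrap_reps >= 1L,
            cfg$expansion_threshold >= 1L)
  class(cfg) <- "SurveyConfig"
  cfg
}

# "id|taxon" and "Genus species|id" header styles are sniffed; a taxon
# map is the fallback.
parseTaxa <- function(ids, taxon_map = NULL) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  out <- vapply(parts, function(p) {
    if (length(p) == 2L) {
      if (grepl(" ", p[1L])) c(id = p[2L], taxon = p[1L])
      else c(id = p[1L], taxon = p[2L])
    } else c(id = p[1L], taxon = NA_character_)
  }, character(2L))
  id <- unname(out["id", ])
  taxon <- unname(out["taxon", ])
  if (!is.null(taxon_map)) {
    if (is.character(taxon_map)) taxon_map <- read.delim(taxon_map)
    hit <- match(id, taxon_map$id)
    taxon[is.na(taxon)] <- taxon_map$taxon[hit[is.na(taxon)]]
  }
  taxon[is.na(taxon)] <- "unknown"
  data.frame(id = id, taxon = taxon, stringsAsFactors = FALSE)
}

readSequences <- function(x) {
  if (is(x, "XStringSet")) return(x)
  if (is.character(x) && !is.null(names(x))) return(AAStringSet(x))
  if (is.character(x)) {
    sets <- lapply(x, readAAStringSet)
    return(do.call(c, sets))
  }
  stop("cannot interpret sequence input")
}

# Stable short hash of the configuration for report provenance (FNV-1a).
configHash <- function(cfg) {
  drop <- c("proteomes", "seed_aln", "out_dir", "taxon_map")
  ser <- as.character(toJSON(cfg[sort(setdiff(names(cfg), drop))],
                             auto_unbox = TRUE, digits = NA,
                             force = TRUE))
  h <- 2166136261
  for (b in utf8ToInt(ser)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full family survey
#'
#' Stages: profile construction from the seed alignment; E-value
#' calibration; domain search at the E-value cutoff; coverage filter;
#' reference-column mapping; redundancy removal; cysteine-profile,
#' sequon and signal-peptide classification; per-profile conservation;
#' NJ phylogeny with bootstrap, clade assignment and expansion
#' detection. Identical configuration and seed give identical reports.
#'
#' @param config A [surveyConfig()].
#' @return Invisibly, the survey report list: `hits`, `calls` (the
#'   per-sequence table), `species`, `expansions`, `conservation` (per
#'   profile group), `tree`, `clades`, and `meta`. Artifacts are written
#'   to `out_dir` when set.
#' @export
runSurvey <- function(config) {
  stopifnot(inherits(config, "SurveyConfig"))
  surveyPipeline(config, skip_search = FALSE)
}

#' Classification-only mode
#'
#' Runs the pipeline from the mapping stage onward on sequences that are
#' already known family members (e.g. a published family set): every
#' sequence is Viterbi-aligned to the profile, and no E-value filter is
#' applied. Downstream artifacts are identical to [runSurvey()]'s.
#'
#' @param seqs Sequences ([Biostrings::AAStringSet] or FASTA path).
#' @param seed_aln Seed alignment (path or [Biostrings::AAStringSet]).
#' @param config A [surveyConfig()]; its `proteomes`/`seed_aln` fields
#'   are overridden by the arguments.
#' @return As [runSurvey()].
#' @export
classificationOnlyMode <- function(seqs, seed_aln,
                                   config = surveyConfig()) {
  config$proteomes <- seqs
  config$seed_aln <- seed_aln
  surveyPipeline(config, skip_search = TRUE)
}

surveyPipeline <- function(config, skip_search = FALSE) {
  seqs <- readSequences(config$proteomes)
  meta <- list(config_hash = configHash(config), seed = config$seed,
               n_input = length(seqs),
               package_version = as.character(utils::packageVersion("epdrsurvey")))
  if (length(seqs) == 0L) {
    warning("empty proteome: nothing to survey")
    report <- list(hits = NULL, calls = NULL, species = NULL,
                   expansions = NULL, conservation = list(), tree = NULL,
                   clades = NULL, meta = meta)
    writeArtifacts(report, config)
    return(invisible(report))
  }
  seed_aln <- readSequences(config$seed_aln)
  tx <- parseTaxa(names(seqs), config$taxon_map)
  names(seqs) <- tx$id
  taxa <- setNames(tx$taxon, tx$id)

  hmm <- buildProfile(seed_aln,
                      match_occupancy_threshold = config$occupancy_threshold,
                      pseudocount = config$pseudocount)

  if (skip_search) {
    res <- scoreSet(hmm, seqs, do_path = TRUE)
    paths <- lapply(res, `[[`, "path")
    bits <- vapply(res, function(r) r$forward / log(2), numeric(1L))
    hits <- data.frame(id = names(seqs), bitscore = bits,
                       evalue = NA_real_, start = NA_integer_,
                       end = NA_integer_, pass = TRUE,
                       path = I(unname(paths)), stringsAsFactors = FALSE)
  } else {
    cal <- calibrateEvalue(hmm, n_random = config$n_random,
                           seed = config$seed + 1L, N = length(seqs))
    hits <- searchDomains(hmm, seqs, cal, cutoff = config$evalue_cutoff)
    meta$calibration <- c(lambda = cal@lambda, mu = cal@mu)
  }

  maps <- lapply(seq_len(nrow(hits)), function(i)
    mapToColumns(hits$path[[i]], hmm))
  names(maps) <- hits$id
  cover <- vapply(maps, columnCoverage, numeric(1L), hmm = hmm)
  accepted <- hits$id[hits$pass & cover >= config$coverage_threshold]
  meta$n_pass_evalue <- sum(hits$pass)
  meta$n_accepted <- length(accepted)

  if (length(accepted) == 0L) {
    warning("no sequences accepted")
    report <- list(hits = hits[, setdiff(names(hits), "path")],
                   calls = NULL, species = NULL, expansions = NULL,
                   conservation = list(), tree = NULL, clades = NULL,
                   meta = meta)
    writeArtifacts(report, config)
    return(invisible(report))
  }

  fam_seqs <- seqs[accepted]
  fam_maps <- maps[accepted]
  aln <- impliedAlignment(fam_seqs, fam_maps,
                          ncol = max(columnMap(hmm)))
  dd <- deduplicate(aln, config$dedup_threshold)
  retained <- dd$retained
  meta$n_retained <- length(retained)

  fam_seqs <- fam_seqs[retained]
  fam_maps <- fam_maps[retained]
  aln <- aln[retained]

  calls <- classifySequences(fam_seqs, fam_maps,
                             strict = config$strict_calls,
                             max_distance = config$max_call_distance,
                             canon = config$canonical,
                             ref_ncol = nMatchStates(hmm))
  calls$taxon <- unname(taxa[calls$id])
  if (!skip_search)
    calls$evalue <- hits$evalue[match(calls$id, hits$id)]

  conservation <- lapply(split(calls$id, calls$profile), function(ids)
    columnProfile(aln, group = ids))

  tree <- NULL; clades <- NULL
  if (length(retained) >= 3L) {
    tree <- bootstrapSupport(aln, reps = config$bootstrap_reps,
                             seed = config$seed + 2L,
                             model = config$distance_model)
    prof <- setNames(calls$profile, calls$id)
    clades <- tryCatch(assignClades(tree, prof),
                       error = function(e) {
                         warning(conditionMessage(e))
                         NULL
                       })
    if (!is.null(clades)) calls$clade <- unname(clades[calls$id])
  } else {
    warning("fewer than 3 retained sequences: tree stage skipped")
  }

  exps <- detectExpansions(setNames(calls$taxon, calls$id), tree,
                           count_threshold = config$expansion_threshold,
                           clade_min = config$clade_min)

  report <- list(hits = hits[, setdiff(names(hits), "path")],
                 calls = calls, species = exps$species,
                 expansions = exps, conservation = conservation,
                 tree = tree, clades = clades, meta = meta,
                 alignment = aln)
  writeArtifacts(report, config, fam_seqs)
  invisible(report)
}

writeArtifacts <- function(report, config, fam_seqs = NULL) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(fam_seqs))
    writeXStringSet(fam_seqs, file.path(dir, "accepted.fasta"))
  if (!is.null(report$hits))
    writeHits(report$hits, file.path(dir, "hits.tsv"))
  if (!is.null(report$calls))
    write.table(report$calls, file.path(dir, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  for (p in names(report$conservation))
    writeConservation(report$conservation[[p]],
                      file.path(dir, sprintf("conservation_profile%s.tsv", p)))
  if (!is.null(report$tree))
    write.tree(report$tree, file.path(dir, "tree.nwk"))
  json <- report[c("species", "meta")]
  json$expansions <- if (!is.null(report$expansions))
    report$expansions[c("species", "clades")]
  json$clade_counts <- if (!is.null(report$clades))
    as.list(table(report$clades))
  write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
             digits = NA, force = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Summaries of a survey report by profile, clade and species
#'
#' @param report Report list from [runSurvey()].
#' @return A list: `by_profile`, `by_clade`, `by_species` (count tables
#'   as data frames), `profile_by_clade` (cross-tabulation), `presence`
#'   (taxon x profile presence/absence matrix).
#' @export
summarizeByGroup <- function(report) {
  calls <- report$calls
  if (is.null(calls) || nrow(calls) == 0L)
    return(list(by_profile = data.frame(), by_clade = data.frame(),
                by_species = data.frame(),
                profile_by_clade = table(character(), character()),
                presence = matrix(0L, 0L, 0L)))
  tab <- function(x) {
    t <- table(x)
    data.frame(group = names(t), n = as.integer(t),
               stringsAsFactors = FALSE)
  }
  clade <- if ("clade" %in% names(calls)) calls$clade
           else rep("unassigned", nrow(calls))
  pres <- table(calls$taxon, calls$profile) > 0L
  list(by_profile = tab(calls$profile),
       by_clade = tab(clade),
       by_species = tab(calls$taxon),
       profile_by_clade = table(profile = calls$profile, clade = clade),
       presence = pres * 1L)
}
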