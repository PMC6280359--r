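Package: epdrsurvey
Title: Profile-Based Survey and Classification of Ependymin-Related Proteins
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for surveying ependymin-related (EPDR) proteins in
    predicted proteomes. Builds a profile hidden Markov model of the
    ependymin domain from a seed alignment and searches protein sets with
    forward-algorithm bit scores and Gumbel-calibrated E-values; expresses
    hits in the reference alignment coordinate system; classifies sequences
    into the family's three conserved-cysteine profiles; annotates
    N-glycosylation sequons and signal peptides with deterministic
    heuristics; computes per-column conservation and sequence-logo
    matrices; and infers bootstrap neighbor-joining phylogenies with
    two-clade assignment and lineage-specific expansion detection. A
    synthetic family generator with planted, recoverable ground truth
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
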