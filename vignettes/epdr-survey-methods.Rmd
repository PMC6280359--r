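---
title: "Methods: profile-based EPDR family surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-based EPDR family surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette describes the models and procedures implemented in
`epdrsurvey`, the parameters that matter, what the synthetic data
generator does and does not emulate, and the design choices made where
the design was genuinely open.

## The survey model

Ependymin-related proteins (EPDRs) are ~200-residue secreted
glycoproteins whose family identity rests on a sparse set of conserved
residues rather than overall similarity. The survey pipeline treats
family membership and typology as two separate questions:

1. **Membership** is decided by a profile hidden Markov model of the
   ependymin domain. The profile is built from a seed alignment:
   columns with residue occupancy at or above 0.5 (inclusive) become
   match states; match emissions are smoothed as
   $(n_a + c\,q_a) / (n + c)$ with pseudocount weight $c$ (default 1)
   and background $q$ estimated from all seed residues with a Laplace
   count; transitions are estimated from the observed per-row state
   paths, smoothed with a structured prior (match continuation 0.93,
   insert-open 0.02, delete-open 0.05; gap states return to the match
   track with probability 0.7–0.75, scaled by the same weight $c$).
   The structured prior matters: with an indel-poor seed alignment a
   uniform prior over outgoing transitions makes long delete chains
   nearly free, and the decoded alignments detour around conserved
   columns. Scoring is glocal — the whole profile, local in the
   sequence — because the domain spans almost the entire protein. The
   bit score is the forward-algorithm log-odds against an i.i.d.
   background null, computed in log space (stable to at least
   10,000-residue sequences).

2. **Typology** is decided in the seed alignment's column coordinate
   system. Each accepted hit's residues are mapped to reference columns
   and the six canonical cysteine columns {23, 24, 94, 107, 148, 186}
   are tested for cysteine occupancy. The three templates are
   profile 1 = {23, 94, 148, 186}, profile 2 = all six, profile 3 =
   {23, 94, 107, 186}. Strict calling requires an exact template match;
   tolerant calling (the default, distance budget 1) assigns the
   nearest template by Hamming distance over the six-column occupancy
   vector, with ties falling back to `atypical`. Tolerant-by-default
   mirrors how deviant family members that lost or gained one cysteine
   are still recognisably members of their clade; strict mode is used
   whenever exact template recovery is the question.

### E-values

The 1e-5 acceptance cutoff presupposes an E-value. The package
calibrates one by scoring `n_random` (default 1000) sequences drawn
i.i.d. from the profile's background distribution, fitting a Gumbel
distribution to the bit scores by maximum likelihood (the standard
fixed-point equation for the scale, solved with `uniroot`), and setting
$E(S) = N e^{-\lambda (S - \mu)}$ clamped to $[0, N]$ with $N$ the
number of searched sequences. Any monotone calibration preserves the
semantics of a rank cutoff; the Gumbel form matches the expected
extreme-value behaviour of alignment scores. The cutoff is treated as a
best-hit-per-sequence E-value.

### Alignment decoding

Reference-column maps are computed from posterior-decoded state paths
(forward–backward match posteriors combined by a monotone
maximum-expected-accuracy alignment, with a small posterior penalty of
0.05 to suppress noise matches), not from the single Viterbi path. The
Viterbi score and path remain available from `scoreSequence()` and are
used for the score-level invariants. The reason is robustness: under
high within-family divergence the single best path occasionally takes a
locally lucky detour that the bulk of the posterior mass does not
support, and a single misplaced canonical column flips a strict profile
call. Posterior decoding is the field-standard remedy.

### Conservation

Per-column residue frequencies are computed over non-gap residues only,
with occupancy reported separately; this keeps the information content
$IC_j = \log_2 20 - H_j$ bounded in $[0, \log_2 20]$ regardless of gap
structure. No small-sample correction is applied by default because
survey group sizes are far above 20 sequences; single-column analyses at
tiny $n$ should interpret IC accordingly. Logo matrices are emitted in
both information scaling (`height = f * IC`, column sums equal IC) and
raw frequency scaling, since both conventions are in active use.
"Conserved" calls use a frequency threshold, default 0.9.

### Phylogeny

Tree inference is distance-based by design: Poisson-corrected
($d = -\ln(1-p)$, $p$ capped at 0.95 as a saturation guard)
pairwise-deletion distances and Saitou–Nei neighbor joining, with
deterministic tie-breaking (smallest index pair) and negative branch
lengths clamped to zero with the excess moved to the sibling edge.
This is a deliberate methodological substitution for maximum-likelihood
or Bayesian inference: it is deterministic, fast enough to bootstrap
a few hundred leaves in seconds, provably consistent on additive
matrices (tested), and sufficient to exercise the two-clade and
expansion logic. It is *not* presented as a reproduction of
model-based support values, which are out of scope.

Bootstrap supports resample alignment columns with replacement
(default 100 replicates) and count each original internal-edge
bipartition among replicate NJ trees. Clade assignment scans internal
edges for the bipartition minimising misplacement of profile-1 versus
profile-2 anchor leaves; among equally separating edges the smallest
profile-1-majority side wins, so non-anchor leaves (profile 3,
atypical) are not pulled into clade 1 by ties. Profile-3 and atypical
leaves inherit the label of their side. If no edge beats the trivial
split, every leaf is `unassigned` and a warning is raised. Expansions
are flagged per species at a count threshold (default 15, inclusive);
maximal monophyletic same-taxon clades of at least 2 leaves are
reported as duplication evidence.

## The synthetic family generator

`generateFamily()` emulates the statistical structure the analysis
assumes, with every planted feature recorded in a truth table:

- a 200-column reference space with two fixed clade consensus backbones
  (embedded constants differing at ~half of the non-canonical columns —
  the deep divergence signal between the family's two clades);
- cysteines at exactly the canonical columns of the planted profile, a
  proline at column 150, and serines at non-profile canonical columns;
- per-site substitutions away from the consensus at `mutation_rate`
  (default 0.4; canonical columns are never mutated, and substitutions
  never introduce cysteine — the family's cysteine architecture is
  under strong selection in a disulfide-bonded secreted protein);
- indels at `indel_rate` (default 0.02 per site, split between
  insertions of 1–3 residues and single-column deletions) outside a
  ±5-column guard band around canonical columns, so planted residues
  are never deleted and their local alignment context stays
  unambiguous;
- an 18-residue hydrophobic signal peptide ending in an A-X-A cleavage
  motif; N-X-S/T sequons at residue offsets 3 and 27 upstream of the
  column-94 cysteine (the fish-type arrangement);
- a background-composition C-terminal tail sized so mature-protein
  lengths follow a discretised symmetric distribution with median 213
  and half inter-quartile width 15 (the family reports only a median
  and a length distribution, not a parametric form);
- optional expansion paralogs: part of the profile-1 quota shares a
  subfamily ancestor (0.6 of the mutation budget) with member-specific
  divergence (0.5 of the budget), so the group is tight enough to form
  a monophyletic same-taxon clade; family members are otherwise spread
  round-robin over `n_taxa` (default 30) taxa;
- decoys drawn i.i.d. from the background composition with the same
  length model, and a truth table that round-trips through TSV.

What the generator does **not** emulate: real phylogenetic
autocorrelation (every family member is an independent draw from its
clade consensus, so within-clade tree structure is star-like apart from
planted paralog clusters), transcriptome assembly noise, fragmentary
gene models, compositional bias of real proteomes, nucleotide-level
evolution, or genomic clustering of tandem duplicates. Passing the
planted-truth tests therefore demonstrates that the pipeline's logic is
correct under the family's statistical regime — not that its accuracy
transfers unchanged to real proteomes.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `match_occupancy_threshold` | 0.5 (inclusive) | fraction of rows | standard profile construction |
| `pseudocount` | 1 | count weight | simplest defensible smoothing |
| `evalue_cutoff` | 1e-5 | expected false hits | the survey's acceptance threshold |
| `n_random` | 1000 | sequences | Gumbel fit stability (floor 100) |
| `dedup_threshold` | 0.97 | pairwise identity | "identical or very similar"; no published number |
| `coverage_threshold` | 0.6 | fraction of match states | discards incomplete domains |
| `trim_threshold` | 0.5 | column occupancy | removes sequence-specific insertions |
| `conservation_threshold` | 0.9 | residue frequency | "conserved" without a published number |
| `max_call_distance` | 1 | Hamming distance | tolerant typing of one-cysteine deviants |
| `bootstrap_reps` | 100 | replicates | conventional support estimation |
| `expansion_threshold` | 15 | genes per species | the family's "large expansion" bound (inclusive) |
| signal-peptide window / threshold | 8 / 2.5 | residues / mean KD | calibrated on the generator: ~99% sensitivity on planted signals, ~4% false positives on background; the hydrophobic core must start within residues 1–12 and an A/G/S cleavage-permissive residue must follow within positions 15–30 |
| `mutation_rate` | 0.4 | per-site probability | within-profile divergence is not published; exposed in the config |

Coordinates are 1-based and inclusive throughout, in the trimmed
reference alignment's column space; `trimAlignment()` returns the
old-to-new renumbering map so either coordinate frame can be recovered.

## Numerical choices

- All dynamic programming in natural-log space with pairwise
  `log1p(exp())` combination; scores convert to bits at the interface.
- Unknown residue symbols are an error in strict mode; otherwise scored
  as ambiguity-neutral (zero log-odds).
- Gumbel fitting brackets the scale at 1/100 to 100 times the moment
  estimate and refuses degenerate (zero-variance) score sets.
- NJ tie-breaks, the negative-branch-length rule and pairwise deletion
  are fixed exactly as stated above so every tree is reproducible;
  bootstrap and simulation randomness runs through explicit seeds.
- The survey derives stage seeds (calibration, bootstrap) from the
  single configured seed, so a rerun with the same configuration is
  byte-identical, and the report embeds a configuration hash.

## Problem sizes

The test suite validates the full default study bundle — 100 sequences
per profile plus 1000 decoys, 100 bootstrap replicates — in a few
minutes on one CPU; unit tests use 15–50 sequences per profile, toy
profiles of up to 4 match states for brute-force path enumeration, and
50 random 6–10-leaf additive matrices for NJ consistency. These sizes
were chosen to keep every oracle exhaustive where exhaustiveness is the
point (all 2^6 occupancy vectors, all 20^3 tripeptides, all state
paths) and statistically stable where recovery rates are asserted.

## Known limitations

- At `mutation_rate` 0.4, roughly 1 in 1200 generated family sequences
  has a C-terminal stretch that genuinely aligns better a few columns
  shifted — the planted alignment is not the posterior mode, and both
  Viterbi and posterior decoding prefer the shift, which converts one
  strict profile call to `atypical` (tolerant calls are unaffected).
  The generator does not reject such draws, since filtering on the
  classifier's own success would make the recovery tests circular. The
  fixed default bundle is unaffected.
- Distance/NJ trees with column-resampling bootstrap are a desk-scale
  substitute for model-based inference; deep-branch supports are not
  comparable to published ML bootstrap or posterior values.
- The signal-peptide and sequon annotations are deterministic
  heuristics. The sequon rule N-X(≠P)-S/T is the deterministic core of
  N-glycosylation prediction, and the hydropathy rule is calibrated
  only on synthetic data; neither claims the accuracy of trained
  predictors, and no glycosylation-likelihood or cleavage-site accuracy
  is asserted.
- The E-value calibration is a package decision (background-sequence
  Gumbel fit), not a reimplementation of any specific search tool's
  internal calibration; absolute E-values differ from other tools, the
  cutoff semantics do not.
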