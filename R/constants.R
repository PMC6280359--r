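# Family-level constants: alphabet, composition, hydropathy, the canonical
# cysteine columns of the reference alignment, and the fixed consensus
# backbones used by the synthetic generator.

#' Amino-acid alphabet used throughout the package
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Background amino-acid composition (approximately proteome-wide averages),
# renormalised to sum to 1. Used by the synthetic generator and as the
# default residue prior.
BACKGROUND_FREQS <- local({
  f <- c(A = 0.0825, C = 0.0138, D = 0.0546, E = 0.0672, F = 0.0386,
         G = 0.0707, H = 0.0227, I = 0.0591, K = 0.0580, L = 0.0965,
         M = 0.0241, N = 0.0406, P = 0.0474, Q = 0.0393, R = 0.0553,
         S = 0.0665, T = 0.0536, V = 0.0686, W = 0.0110, Y = 0.0292)
  f[AA_ALPHABET] / sum(f)
})

# Kyte-Doolittle hydropathy scale.
KD_HYDROPATHY <- c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
                   G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
                   M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                   S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

#' Canonical cysteine columns of the EPDR reference alignment
#'
#' Six reference-alignment columns carry the family's conserved cysteines:
#' columns 23, 94 and 186 in all three profiles, plus profile-specific
#' extras (148 for profile 1; 24, 107 and 148 for profile 2; 107 for
#' profile 3). A proline is conserved at column 150. These constants can be
#' overridden in [surveyConfig()] to reuse the machinery on other families.
#'
#' @return A list with elements `universal`, `profile1_extra`,
#'   `profile2_extra`, `profile3_extra`, `proline_column`, and `all`
#'   (the six cysteine columns, sorted).
#' @export
#' @examples
#' canonicalColumns()$universal
canonicalColumns <- function() {
  list(universal      = c(23L, 94L, 186L),
       profile1_extra = 148L,
       profile2_extra = c(24L, 107L, 148L),
       profile3_extra = 107L,
       proline_column = 150L,
       all            = c(23L, 24L, 94L, 107L, 148L, 186L))
}

#' Cysteine occupancy templates of the three EPDR profiles
#'
#' Each template is the set of canonical columns occupied by cysteine in
#' that profile: profile 1 = \{23, 94, 148, 186\}, profile 2 =
#' \{23, 24, 94, 107, 148, 186\}, profile 3 = \{23, 94, 107, 186\}.
#'
#' @param canon Canonical column definition, see [canonicalColumns()].
#' @return Named list of integer vectors (`"1"`, `"2"`, `"3"`).
#' @export
profileTemplates <- function(canon = canonicalColumns()) {
  list("1" = sort(c(canon$universal, canon$profile1_extra)),
       "2" = sort(c(canon$universal, canon$profile2_extra)),
       "3" = sort(c(canon$universal, canon$profile3_extra)))
}

# Reference column space used by the synthetic generator.
REF_NCOL <- 200L

# Fixed consensus backbones for the two deep clades. Non-cysteine residues
# throughout; the six canonical columns hold serine placeholders that the
# generator overwrites with cysteine according to the planted profile, and
# column 150 holds the conserved proline. The two backbones differ at 96 of
# the 193 non-canonical columns, providing the deep two-clade divergence
# signal.
CLADE_CONSENSUS <- c(
  "1" = paste0(
    "AIDLEGVKQTSSPYGFSKSQTMSSTKSIPISRVNYPTTGGYEAIIDQGAA",
    "TTSVHALFRIYREHTRRPNFLNWFLLVLARKFHRVQANEAIQTSNKFGKL",
    "MSVNGTSAHHSAANPAANRIPFKPEPPDLNNADDVVLVAPEERVTKPSLP",
    "TEGLNKLIKISEATRPLRQHSFHIDETMKDVFNGGSLSLHPSGLMSSWIA"),
  "2" = paste0(
    "AILEEGVKREPSQYLESKKNTMSSTKLISSLRNNYPTVGAMEAQIDKGAN",
    "DAEVHILFRTTAIYTRRPNFENGFLLILTRSAFVKAGNIHIETSNGFNKT",
    "METNGTSGHHVAQNEAEKFIEFKITPPFLNNWDDRVLLASSARVTKNSLP",
    "EERELDLSTPSLFTIALPLELFPIGEKMKDIFNQNSLSFLPSGRMVFEPA"))

# Residues drawn for the hydrophobic core of planted signal peptides.
SIGNAL_CORE_FREQS <- local({
  f <- c(L = 0.30, A = 0.18, V = 0.15, I = 0.12, F = 0.10, M = 0.08,
         W = 0.04, S = 0.03)
  f / sum(f)
})

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}
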