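## Canonical residue alphabet and grouped-alphabet definitions shared by all
## encoders.  Order is alphabetical single-letter code with 'O' as the 21st
## dummy symbol; every encoder indexes residues through this order.

#' Canonical amino-acid alphabets
#'
#' `AA20` is the canonical ordering of the 20 standard amino acids
#' ("ACDEFGHIKLMNPQRSTVWY"); `AA21` appends the dummy symbol `"O"` used for
#' non-standard letters and window padding.
#'
#' @format Character vectors of length 20 and 21.
#' @export
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @rdname AA20
#' @export
AA21 <- c(AA20, "O")

## Residue groupings used by the grouped-composition encoders.  Each is a
## named list mapping group label -> residue set.

# EGAAC five physicochemical categories
EGAAC_GROUPS <- list(
  g1.aliphatic = strsplit("GAVLMI", "")[[1]],
  g2.aromatic  = strsplit("FYW", "")[[1]],
  g3.positive  = strsplit("KRH", "")[[1]],
  g4.negative  = strsplit("DE", "")[[1]],
  g5.uncharged = strsplit("STCPNQ", "")[[1]]
)

# EBAG four-class reduced alphabet (dummy maps to "X")
EBAG_GROUPS <- list(
  C1.hydrophobic = strsplit("AFGILMPVW", "")[[1]],
  C2.polar       = strsplit("CNQSTY", "")[[1]],
  C3.acidic      = strsplit("DE", "")[[1]],
  C4.basic       = strsplit("HKR", "")[[1]]
)

# Side-chain (R group) six categories
SIDECHAIN_GROUPS <- list(
  aliphatic = strsplit("AILMV", "")[[1]],
  aromatic  = strsplit("FWY", "")[[1]],
  polar     = strsplit("NCQST", "")[[1]],
  acidic    = strsplit("DE", "")[[1]],
  basic     = strsplit("RHK", "")[[1]],
  unique    = strsplit("GP", "")[[1]]
)

# Eight-letter reduced alphabet
REDUCED8_GROUPS <- list(
  acid       = c("D", "E"),
  basic      = c("H", "K", "R"),
  aromatic   = c("F", "W", "Y"),
  amide      = c("N", "Q"),
  hydroxyl   = c("S", "T"),
  sulfur     = c("C", "M"),
  aliphatic1 = c("A", "G", "P"),
  aliphatic2 = c("I", "L", "V")
)

# Sandberg z-scales (z1 lipophilicity, z2 steric bulk, z3 polarity,
# z4/z5 electronic properties), one 5-vector per standard residue.
ZSCALES <- matrix(c(
   0.24, -2.32,  0.60, -0.14,  1.30,  # A
   0.84, -1.67,  3.71,  0.18, -2.65,  # C
   3.98,  0.93,  1.93, -2.46,  0.75,  # D
   3.11,  0.26, -0.11, -3.04, -0.25,  # E
  -4.22,  1.94,  1.06,  0.54, -0.62,  # F
   2.05, -4.06,  0.36, -0.82, -0.38,  # G
   2.47,  1.95,  0.26,  3.90,  0.09,  # H
  -3.89, -1.73, -1.71, -0.84,  0.26,  # I
   2.29,  0.89, -2.49,  1.49,  0.31,  # K
  -4.28, -1.30, -1.49, -0.72,  0.84,  # L
  -2.85, -0.22,  0.47,  1.94, -0.98,  # M
   3.05,  1.62,  1.04, -1.15,  1.61,  # N
  -1.66,  0.27,  1.84,  0.70,  2.00,  # P
   1.75,  0.50, -1.44, -1.34,  0.66,  # Q
   3.52,  2.50, -3.50,  1.99, -0.17,  # R
   2.39, -1.07,  1.15, -1.39,  0.67,  # S
   0.75, -2.18, -1.12, -1.46, -0.40,  # T
  -2.59, -2.64, -1.54, -0.85, -0.02,  # V
  -4.36,  3.94,  0.59,  3.44, -1.59,  # W
  -2.54,  2.44,  0.43,  0.04, -1.47   # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(AA20, paste0("z", 1:5)))

# Standard genetic-code codon multiplicities (stop codons excluded, total 61)
CODON_COUNTS <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3,
                  K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6,
                  T = 4, V = 4, W = 1, Y = 2)
CODON_TOTAL <- 61

.blosum_env <- new.env(parent = emptyenv())

#' The bundled BLOSUM62 substitution matrix restricted to the 20 standard
#' amino acids, in canonical [AA20] order.
#'
#' @return A 20x20 integer matrix.
#' @export
blosum62_matrix <- function() {
  if (is.null(.blosum_env$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$b62 <- e$BLOSUM62[AA20, AA20]
  }
  .blosum_env$b62
}

#' Canonicalize a protein sequence
#'
#' Uppercases the sequence and replaces every letter outside the 20 standard
#' amino acids (B, J, U, X, Z, ...) with the dummy symbol `"O"`, so all
#' downstream encoders operate on a closed 21-letter alphabet.
#'
#' @param x Character vector of sequences.
#' @return Character vector of the same length over `AA21`.
#' @export
canonicalize_sequence <- function(x) {
  x <- toupper(x)
  vapply(strsplit(x, ""), function(ch) {
    ch[!(ch %in% AA20)] <- "O"
    paste0(ch, collapse = "")
  }, character(1))
}

# split a fragment string into a residue vector; internal
split_residues <- function(s) strsplit(s, "")[[1]]

# map residues to canonical 1..21 index
residue_index <- function(res) match(res, AA21)

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
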