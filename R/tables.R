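## Residue-level lookup tables shared across modules.

#' @importFrom methods new validObject is setValidity slot
#' @importFrom stats hclust as.dist rexp runif rpois setNames
#' @importFrom utils head tail write.table read.table
NULL

# IUPAC nucleotide ambiguity codes and their concrete expansions
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle (1982) residue hydropathy values; X scores 0
KD_SCALE <- c(
  I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5, X = 0
)

# Average (isotope-abundance weighted) residue masses, Da; protein mass adds
# one water (18.01528 Da)
AA_AVG_MASS <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_AVG_MASS <- 18.01528

#' BLOSUM62 substitution scores
#'
#' Returns the BLOSUM62 matrix shipped with Biostrings, restricted to the 20
#' standard amino acids plus X.  Symmetric; used throughout for alignment,
#' similarity statistics and the "similar residue" relation (score > 0).
#'
#' @return Integer matrix with dimnames over the 21 residue codes.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  keep <- c(AA20, "X")
  e$BLOSUM62[keep, keep]
}

# split a residue string into a character vector
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.is_valid_dna <- function(chars) all(chars %in% names(IUPAC_COMPLEMENT))
# '*' admitted so translations can carry stop codons; FASTA input still
# rejects it (non-letter)
.is_valid_protein <- function(chars) all(chars %in% c(AA20, "X", "*"))
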