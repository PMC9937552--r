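#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail write.table modifyList
NULL

## Canonical 20-letter amino-acid alphabet, alphabetical one-letter order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Three-letter -> one-letter translation; anything else maps to "X".
AA_THREE2ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Translate three-letter residue names to one-letter codes
#'
#' Unknown or modified residue names (anything outside the standard 20)
#' are mapped to \code{"X"}.
#'
#' @param resid Character vector of three-letter residue names.
#' @return Character vector of one-letter codes.
#' @keywords internal
aaThreeToOne <- function(resid) {
  out <- AA_THREE2ONE[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}

## Kyte-Doolittle hydropathy index.
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2, X = 0
)

## Robinson-Robinson background amino-acid frequencies (the standard
## sequence-database composition used by profile methods), indexed by
## one-letter code and renormalised to sum exactly to 1.
ROBINSON_BACKGROUND <- local({
  f <- c(
    A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
    G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
    M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
    S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216
  )
  f <- f[AA_ALPHABET]
  f / sum(f)
})

## Round half-up to `digits` decimals (base round() is half-even).
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## as.character() that keeps names (base as.character strips attributes).
asNamedChar <- function(x) {
  nm <- names(x)
  out <- as.character(x)
  if (!is.null(nm)) names(out) <- nm
  out
}

## Split an amino-acid string into a character vector.
aaChars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1]]

## 3D Euclidean distance between rows of coordinate matrices.
rowDist <- function(a, b) sqrt(rowSums((a - b)^2))

## Deterministic child seed derived from a base seed (kept < 2^31).
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + as.double(k) * 12347L) %% 2147483647)
}
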