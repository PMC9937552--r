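# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (enumeration, grid search, per-column recomputation) and never call
# the code paths they check.

AA_ALPHABET_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

aaChars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1]]

# Fixed-width PDB ATOM line (wwPDB v3.3 columns).
pdbAtomLine <- function(serial, name, resName, chain, resSeq, x, y, z,
                        occ = 1, b = 90, elem = substr(name, 1, 1),
                        altLoc = " ", iCode = " ") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), altLoc, resName, chain, resSeq, iCode,
          x, y, z, occ, b, elem)
}

# Minimal 3-residue PDB (sequence ACD) with one SG on the Cys.
tinyPdbText <- function() {
  c(pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0, b = 95),
    pdbAtomLine(2, "CA", "CYS", "A", 2, 3.8, 0, 0, b = 88),
    pdbAtomLine(3, "SG", "CYS", "A", 2, 4.8, 1, 0, b = 88),
    pdbAtomLine(4, "CA", "ASP", "A", 3, 7.6, 0, 0, b = 77),
    "TER", "END")
}

writeTinyPdb <- function(lines = tinyPdbText()) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Exhaustive matching oracle: all partial matchings over candidate Cys pairs
# within the cutoff; picks max cardinality, then min total distance, then
# lexicographic order. Coordinates: n x 3 matrix of SG positions.
bruteForceMatching <- function(sg, cutoff = 2.5) {
  n <- nrow(sg)
  d <- as.matrix(dist(sg))
  edges <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(edges) == 0L) return(matrix(integer(), ncol = 2))
  best <- NULL
  bestScore <- NULL
  enum <- function(eIdx, used, chosen) {
    if (eIdx > nrow(edges)) {
      sel <- edges[chosen, , drop = FALSE]
      sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
      score <- list(n = nrow(sel), tot = sum(d[sel]),
                    lex = as.vector(t(sel)))
      replace <- is.null(bestScore) ||
        score$n > bestScore$n ||
        (score$n == bestScore$n && score$tot < bestScore$tot - 1e-12) ||
        (score$n == bestScore$n && abs(score$tot - bestScore$tot) <= 1e-12 &&
           !identical(score$lex, bestScore$lex) &&
           isTRUE(all(score$lex[which(score$lex != bestScore$lex)[1]] <
                        bestScore$lex[which(score$lex != bestScore$lex)[1]])))
      if (replace) { best <<- sel; bestScore <<- score }
      return(invisible(NULL))
    }
    i <- edges[eIdx, 1]; j <- edges[eIdx, 2]
    if (!used[i] && !used[j]) {
      used[c(i, j)] <- TRUE
      enum(eIdx + 1L, used, c(chosen, eIdx))
      used[c(i, j)] <- FALSE
    }
    enum(eIdx + 1L, used, chosen)
  }
  enum(1L, logical(n), integer(0))
  best
}

# Grid-search RMSD oracle: minimises over Euler angles on a fine grid with
# local refinement; translation handled by centering.
gridSearchRmsd <- function(A, B, coarse = 24L) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  rotOf <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  rmsdOf <- function(ang) {
    R <- rotOf(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = coarse + 1L)[-(coarse + 1L)]
  bgrid <- seq(0, pi, length.out = coarse %/% 2L)
  best <- Inf; bestAng <- c(0, 0, 0)
  for (a in grid) for (b in bgrid) for (c in grid) {
    r <- rmsdOf(c(a, b, c))
    if (r < best) { best <- r; bestAng <- c(a, b, c) }
  }
  opt <- optim(bestAng, rmsdOf, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  opt$value
}
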