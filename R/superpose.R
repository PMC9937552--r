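#' Least-squares rigid-body superposition (single cycle)
#'
#' Computes the optimal proper rotation and translation superposing
#' \code{coordsA} onto \code{coordsB} by singular value decomposition of the
#' covariance of the centred point sets, with reflection correction, and the
#' resulting RMSD. This is the single-cycle primitive; see
#' \code{\link{superposeModels}} for the iterated, outlier-rejecting fit.
#'
#' @param coordsA,coordsB N x 3 coordinate matrices (Angstrom), rows paired.
#' @return A \linkS4class{SuperpositionResult}; the transform maps A onto B
#'   (\code{x -> R x + t}). Degenerate (rank-deficient, e.g. collinear) point
#'   sets are flagged \code{"degenerate"}.
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' superRmsd(kabsch(a, a))  # 0
#' @export
kabsch <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (nrow(coordsA) != nrow(coordsB))
    stop("coordinate sets must have equal length", call. = FALSE)
  n <- nrow(coordsA)
  if (n < 3L) stop("at least 3 point pairs are required", call. = FALSE)
  ca <- colMeans(coordsA); cb <- colMeans(coordsB)
  A <- sweep(coordsA, 2, ca); B <- sweep(coordsB, 2, cb)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  flags <- character()
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)) flags <- "degenerate"
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  tvec <- as.numeric(cb - R %*% ca)
  new("SuperpositionResult",
      rotation = R, translation = tvec,
      rmsd = rmsd, rmsd_initial = rmsd,
      n_start = n, n_retained = n, cycles_run = 1L, flags = flags)
}

#' Residue correspondence from a global sequence alignment
#'
#' Globally aligns the two sequences (Needleman-Wunsch) and returns the
#' index pairs at match columns. Pair indices are 1-based positions within
#' each sequence; strictly increasing in both coordinates.
#'
#' @param seqA,seqB Amino-acid strings.
#' @param substitutionMatrix Scoring matrix name (default "BLOSUM62").
#' @param gapOpening,gapExtension Gap penalties (default 10 / 0.5).
#' @return data.frame with columns \code{a}, \code{b}.
#' @export
alignCorrespondence <- function(seqA, seqB, substitutionMatrix = "BLOSUM62",
                                gapOpening = 10, gapExtension = 0.5) {
  if (!nzchar(seqA) || !nzchar(seqB))
    stop("both sequences must be non-empty", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension, type = "global")
  ga <- aaChars(as.character(Biostrings::alignedPattern(pa)))
  gb <- aaChars(as.character(Biostrings::alignedSubject(pa)))
  ia <- cumsum(ga != "-"); ib <- cumsum(gb != "-")
  keep <- ga != "-" & gb != "-"
  data.frame(a = ia[keep], b = ib[keep])
}

#' Sequence-guided superposition of two structure models with outlier rejection
#'
#' Builds the residue correspondence by global sequence alignment (restricted
#' to C-alpha-bearing positions), then iterates: fit the Kabsch superposition
#' on the retained pairs, reject pairs whose per-pair deviation exceeds
#' \code{rejectCutoff}, refit — for up to \code{cycles} cycles or until no
#' pair is rejected. The reported RMSD is over the retained pairs; the
#' initial all-pair RMSD is kept alongside.
#'
#' Defaults (5 cycles, 2.0 A cutoff, BLOSUM62, gap 10/0.5, C-alpha only)
#' mirror the "align"-style behaviour of common structure viewers.
#'
#' @param modelA,modelB \linkS4class{StructureModel} objects (A is mobile).
#' @param cycles Maximum rejection cycles (default 5).
#' @param rejectCutoff Per-pair deviation cutoff in Angstrom (default 2.0).
#' @param substitutionMatrix,gapOpening,gapExtension Alignment parameters.
#' @return A \linkS4class{SuperpositionResult}. Coverage below 50% of the
#'   shorter chain is flagged \code{"low_coverage"}.
#' @examples
#' s <- synthStructure("groupIII_ref", seed = 3)
#' superposeModels(s$model, s$model)
#' @export
superposeModels <- function(modelA, modelB, cycles = 5L, rejectCutoff = 2.0,
                            substitutionMatrix = "BLOSUM62",
                            gapOpening = 10, gapExtension = 0.5) {
  corr <- alignCorrespondence(sequenceOf(modelA), sequenceOf(modelB),
                              substitutionMatrix, gapOpening, gapExtension)
  caA <- atomCoords(modelA, "CA"); caB <- atomCoords(modelB, "CA")
  ridA <- modelA@residues$seq_index[corr$a]
  ridB <- modelB@residues$seq_index[corr$b]
  keep <- as.character(ridA) %in% rownames(caA) &
          as.character(ridB) %in% rownames(caB)
  corr <- corr[keep, , drop = FALSE]
  if (nrow(corr) < 3L)
    stop("fewer than 3 aligned C-alpha pairs; cannot superpose", call. = FALSE)
  xa <- caA[as.character(ridA[keep]), , drop = FALSE]
  xb <- caB[as.character(ridB[keep]), , drop = FALSE]

  nStart <- nrow(xa)
  retained <- rep(TRUE, nStart)
  fit <- NULL
  rmsdInitial <- NA_real_
  cyclesRun <- 0L
  for (cy in seq_len(max(1L, cycles))) {
    if (sum(retained) < 3L)
      stop("fewer than 3 retained pairs after rejection (cycle ", cy,
           "; started with ", nStart, ")", call. = FALSE)
    fit <- kabsch(xa[retained, , drop = FALSE], xb[retained, , drop = FALSE])
    cyclesRun <- cy
    if (cy == 1L) rmsdInitial <- fit@rmsd
    dev <- rowDist(sweep(xa %*% t(fit@rotation), 2, -fit@translation), xb)
    drop <- retained & dev > rejectCutoff
    if (!any(drop) || cy == cycles) break
    retained <- retained & !drop
  }
  flags <- fit@flags
  shorter <- min(nResidues(modelA), nResidues(modelB))
  if (nStart < 0.5 * shorter) flags <- c(flags, "low_coverage")
  new("SuperpositionResult",
      rotation = fit@rotation, translation = fit@translation,
      rmsd = fit@rmsd, rmsd_initial = rmsdInitial,
      n_start = nStart, n_retained = sum(retained),
      cycles_run = cyclesRun, flags = flags)
}

#' Apply a superposition transform to a model's coordinates
#'
#' @param model A \linkS4class{StructureModel}.
#' @param result A \linkS4class{SuperpositionResult}.
#' @return The model with transformed coordinates.
#' @export
applySuperposition <- function(model, result) {
  xyz <- as.matrix(model@atoms[, c("x", "y", "z")])
  moved <- sweep(xyz %*% t(result@rotation), 2, -result@translation)
  model@atoms[, c("x", "y", "z")] <- moved
  model
}
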