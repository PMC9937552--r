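## Desk-scale phylogenetics: entropy-based alignment trimming (a simplified
## stand-in for BMGE-style trimming: normalised Shannon column entropy plus
## a gap-fraction filter, without BLOSUM-similarity smoothing), pairwise
## distances, a neighbor-joining tree with bootstrap supports, and
## anchor-based clade labelling. The classification consumes clade
## membership only, so NJ replaces maximum likelihood here; an externally
## computed Newick tree can be supplied instead at the pipeline level.

asAlnMatrix <- function(msa) {
  nm <- names(msa)
  aln <- as.character(msa)
  if (!is.null(nm)) names(aln) <- nm
  if (length(aln) == 0L) stop("empty alignment", call. = FALSE)
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must have equal width", call. = FALSE)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- if (is.null(names(aln))) paste0("seq", seq_along(aln)) else names(aln)
  m
}

#' Normalised Shannon entropy of one alignment column
#'
#' Entropy of the non-gap residue distribution divided by log2(20), so the
#' value lies in [0, 1]; an all-gap column is defined as 1 (removable).
#'
#' @param msa Named character vector (or AAStringSet) of aligned sequences.
#' @param column Column index.
#' @return Numeric with attribute \code{gap_fraction}.
#' @examples
#' columnEntropy(c("AA", "AA", "AA"), 1)  # 0
#' @export
columnEntropy <- function(msa, column) {
  m <- asAlnMatrix(msa)
  stopifnot(column >= 1L, column <= ncol(m))
  col <- m[, column]
  gap <- col %in% c("-", ".")
  res <- col[!gap]
  H <- if (length(res) == 0L) 1 else {
    p <- table(res) / length(res)
    -sum(p * log2(p)) / log2(20)
  }
  structure(min(max(H, 0), 1), gap_fraction = mean(gap))
}

#' Entropy-based alignment trimming
#'
#' Drops columns whose normalised entropy exceeds \code{cutoff} or whose gap
#' fraction exceeds \code{maxGapFraction}; kept columns preserve their
#' order. The conventional cutoff window for this family's alignments is
#' 0.7-0.9 (default 0.8).
#'
#' @param msa Named character vector (or AAStringSet) of aligned sequences.
#' @param cutoff Normalised entropy cutoff in [0, 1] (default 0.8).
#' @param maxGapFraction Gap-fraction cutoff (default 0.5).
#' @return A \linkS4class{TrimmedAlignment}.
#' @export
entropyTrim <- function(msa, cutoff = 0.8, maxGapFraction = 0.5) {
  m <- asAlnMatrix(msa)
  ent <- numeric(ncol(m)); gapf <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gap <- col %in% c("-", ".")
    gapf[j] <- mean(gap)
    res <- col[!gap]
    ent[j] <- if (length(res) == 0L) 1 else {
      p <- table(res) / length(res)
      min(max(-sum(p * log2(p)) / log2(20), 0), 1)
    }
  }
  keep <- which(ent <= cutoff & gapf <= maxGapFraction)
  if (length(keep) == 0L)
    stop("all columns trimmed; raise the entropy cutoff (", cutoff,
         ") or the gap threshold", call. = FALSE)
  seqs <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  new("TrimmedAlignment", kept_columns = as.integer(keep), sequences = seqs,
      entropy = ent, gap_fraction = gapf)
}

#' Pairwise distance matrix from an alignment
#'
#' p-distance with pairwise deletion of gap sites, optionally
#' Poisson-corrected (d = -ln(1 - p)).
#'
#' @param msa A \linkS4class{TrimmedAlignment}, named character vector or
#'   AAStringSet of aligned sequences.
#' @param model "p" (default) or "poisson".
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(msa, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (is(msa, "TrimmedAlignment")) msa <- msa@sequences
  m <- asAlnMatrix(msa)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 sequences", call. = FALSE)
  isGap <- m %in% c("-", ".", "X")
  dim(isGap) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !isGap[i, ] & !isGap[j, ]
    if (!any(ok))
      stop("no comparable sites between '", rownames(m)[i], "' and '",
           rownames(m)[j], "'", call. = FALSE)
    p <- mean(m[i, ok] != m[j, ok])
    if (model == "poisson") {
      if (p >= 1) stop("saturated pair ('", rownames(m)[i], "', '",
                       rownames(m)[j], "'): Poisson correction undefined",
                       call. = FALSE)
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration on a symmetric distance matrix (delegated to
#' the canonical implementation in \pkg{ape}); negative branch-length
#' estimates are clamped to zero with a message.
#'
#' @param dist Symmetric numeric matrix with zero diagonal and no NA/NaN.
#' @return An \pkg{ape} \code{phylo} tree.
#' @export
njTree <- function(dist) {
  dist <- as.matrix(dist)
  if (any(!is.finite(dist))) stop("distance matrix contains NA/NaN/Inf",
                                  call. = FALSE)
  if (max(abs(dist - t(dist))) > 1e-9) stop("distance matrix must be symmetric",
                                            call. = FALSE)
  if (any(abs(diag(dist)) > 1e-12)) stop("distance matrix diagonal must be zero",
                                         call. = FALSE)
  if (nrow(dist) < 3L) stop("need at least 3 taxa", call. = FALSE)
  tr <- ape::nj(dist)
  if (any(tr$edge.length < 0)) {
    message("clamping ", sum(tr$edge.length < 0),
            " negative NJ branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the point-estimate tree
#' the fraction of replicates containing that bipartition (stored in
#' \code{node.label}).
#'
#' @param msa A \linkS4class{TrimmedAlignment} or aligned sequences.
#' @param nReplicates Number of replicates (default 100; the classic choice
#'   for this family's trees is 1000).
#' @param seed Integer seed.
#' @param model Distance model passed to \code{\link{distanceMatrix}}.
#' @return The NJ tree with per-internal-node supports in [0, 1].
#' @export
bootstrapSupports <- function(msa, nReplicates = 100L, seed = 1L, model = "p") {
  stopifnot(nReplicates >= 1L)
  seqs <- if (is(msa, "TrimmedAlignment")) msa@sequences else as.character(msa)
  m <- asAlnMatrix(seqs)
  point <- njTree(distanceMatrix(seqs, model))
  reps <- withSeed(seed, lapply(seq_len(nReplicates), function(r) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    sub <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    njTree(distanceMatrix(sub, model))
  }))
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  point$node.label <- counts / nReplicates
  point
}

#' Assign group labels to leaves from anchor genes
#'
#' Each anchor leaf carries a known group label. The tree is midpoint-rooted
#' and every non-anchor leaf is assigned by walking toward the root until a
#' clade containing at least one anchor is reached: if all anchors in that
#' clade share one label the leaf takes it, otherwise the leaf is
#' "unassigned".
#'
#' @param tree A \code{phylo} tree.
#' @param anchors Named character vector: names are anchor leaf labels,
#'   values are group labels. Every anchor must be present in the tree.
#' @return Named character vector: leaf -> group label (or "unassigned").
#' @export
cladeAssign <- function(tree, anchors) {
  miss <- setdiff(names(anchors), tree$tip.label)
  if (length(miss))
    stop("anchor leaf/leaves not in tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(anchors)) < 1L) stop("need at least one anchor", call. = FALSE)
  tr <- phangorn::midpoint(tree)
  nTip <- length(tr$tip.label)
  parent <- integer(nTip + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  ## tip sets per node
  tipsOf <- vector("list", nTip + tr$Nnode)
  for (i in seq_len(nTip)) tipsOf[[i]] <- i
  post <- ape::reorder.phylo(tr, "postorder")$edge
  for (e in seq_len(nrow(post)))
    tipsOf[[post[e, 1]]] <- c(tipsOf[[post[e, 1]]], tipsOf[[post[e, 2]]])
  anchorIdx <- match(names(anchors), tr$tip.label)
  out <- setNames(rep("unassigned", nTip), tr$tip.label)
  out[anchorIdx] <- unname(anchors)
  root <- setdiff(unique(tr$edge[, 1]), tr$edge[, 2])
  for (i in setdiff(seq_len(nTip), anchorIdx)) {
    node <- i
    repeat {
      node <- parent[node]
      inside <- intersect(tipsOf[[node]], anchorIdx)
      if (length(inside)) {
        labs <- unique(anchors[match(inside, anchorIdx)])
        if (length(labs) == 1L) out[i] <- labs
        break
      }
      if (node == root) break
    }
  }
  out
}
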