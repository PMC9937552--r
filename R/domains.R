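## Domain architecture and active-site annotation. These are the structural
## features the group/subgroup rules consume: catalytic tetrads, the
## saposin-like nested-disulfide insert, the NAP1 disulfide-stabilised
## surface-loop fold, C-terminal extensions, transmembrane helices, and a
## C-alpha-based strand count for the interdomain sheet.

#' Locate the two catalytic tetrads of a pepsin-like protease
#'
#' The canonical active site is a pair of D[TS]G[ST] tetrads, one in each
#' half of the sequence. The scan takes the first D[TS]G[ST] occurrence in
#' the N-terminal half and the first in the C-terminal half. When a half has
#' no canonical match the scan falls back to (i) the first D-x-G-x tetrad in
#' that half, then (ii) reading the 4-mer aligned to the reference's motif
#' columns after a global alignment to \code{reference}. \code{canonical} is
#' TRUE only if both motifs match D[TS]G[ST] — e.g. a group-IV (SAP1-like)
#' sequence with DLGG/SSVN is non-canonical.
#'
#' @param seq Amino-acid string (length >= 50).
#' @param reference Optional reference for the alignment fallback: a
#'   \code{\link{referenceTopology}} id or list (default "ASPR1").
#' @return list(motif1, pos1, motif2, pos2, canonical, method): motifs are
#'   4-residue strings (empty when nothing was found), methods one of
#'   "canonical", "dxgx", "aligned", "none" per motif.
#' @examples
#' scanActiveSites(referenceTopology("ASPR1")$seq)
#' @export
scanActiveSites <- function(seq, reference = "ASPR1") {
  seq <- as.character(seq)
  n <- nchar(seq)
  if (n < 50L) stop("sequence too short to scan (need >= 50 residues)",
                    call. = FALSE)
  half <- n %/% 2L
  firstIn <- function(pattern, from, to) {
    m <- gregexpr(pattern, seq)[[1]]
    m <- m[m > 0 & m >= from & m <= to - 3L]
    if (length(m)) m[1L] else NA_integer_
  }
  alignedAt <- NULL
  refTplMemo <- NULL
  alignFallback <- function(which) {
    if (is.null(reference)) return(NA_integer_)
    if (is.null(alignedAt)) {
      ref <- if (is.character(reference)) referenceTopology(reference) else reference
      refTplMemo <<- synthTopologyTemplate(switch(ref$id, APA1 = "groupI_A",
                                                  mp4g19220 = "groupII_ref",
                                                  "groupIII_ref"))
      corr <- alignCorrespondence(seq, ref$seq)
      alignedAt <<- function(refPos) {
        hit <- corr$a[match(refPos, corr$b)]
        if (is.na(hit) || hit + 3L > n) NA_integer_ else hit
      }
    }
    alignedAt(as.integer(refTplMemo[[paste0("motif", which)]]["pos"]))
  }
  findMotif <- function(which) {
    rng <- if (which == 1L) c(1L, half) else c(half + 1L, n)
    p <- firstIn("D[TS]G[ST]", rng[1], rng[2])
    method <- "canonical"
    if (is.na(p)) { p <- firstIn("D.G.", rng[1], rng[2]); method <- "dxgx" }
    if (is.na(p)) { p <- alignFallback(which); method <- "aligned" }
    if (is.na(p)) return(list(motif = "", pos = NA_integer_, method = "none"))
    list(motif = substr(seq, p, p + 3L), pos = p, method = method)
  }
  m1 <- findMotif(1L); m2 <- findMotif(2L)
  canonical <- grepl("^D[TS]G[ST]$", m1$motif) && grepl("^D[TS]G[ST]$", m2$motif)
  list(motif1 = m1$motif, pos1 = m1$pos, motif2 = m2$motif, pos2 = m2$pos,
       canonical = canonical, method = c(m1$method, m2$method))
}

#' Detect transmembrane helices by hydropathy
#'
#' Kyte-Doolittle hydropathy averaged over a sliding window; maximal runs of
#' windows whose mean is at least \code{threshold} are reported as TM_helix
#' segments (segment = union of qualifying windows).
#'
#' @param seq Amino-acid string.
#' @param window Window length (default 19, the classic TM window).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @return data.frame(kind, start, end, score); zero rows when none.
#' @export
detectTMHelix <- function(seq, window = 19L, threshold = 1.6) {
  ch <- aaChars(seq)
  n <- length(ch)
  empty <- data.frame(kind = character(), start = integer(), end = integer(),
                      score = numeric())
  if (n < window) return(empty)
  h <- KD_HYDROPATHY[ch]
  h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  ok <- means >= threshold
  if (!any(ok)) return(empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- data.frame(s = starts[r$values], e = ends[r$values])
  data.frame(kind = "TM_helix",
             start = segs$s,
             end = segs$e + window - 1L,
             score = vapply(seq_len(nrow(segs)), function(i)
               max(means[segs$s[i]:segs$e[i]]), numeric(1)))
}

#' Detect a saposin-like domain from nested disulfides
#'
#' The saposin-like insert of group-I proteases is stabilised by three
#' nested disulfides over six consecutive cysteines (pattern a-f, b-e, c-d).
#' The detector slides a window of six consecutive cysteines along the chain
#' and reports the segment spanned by the first window whose internal bonds
#' realise exactly that nesting.
#'
#' @param model A \linkS4class{StructureModel}.
#' @param bonds Bond table from \code{\link{detectDisulfides}}.
#' @return list(start, end) covering the six cysteines, or NULL.
#' @export
detectSaposinLike <- function(model, bonds) {
  cys <- sort(model@residues$seq_index[model@residues$aa == "C"])
  if (length(cys) < 6L || nrow(bonds) == 0L) return(NULL)
  bset <- paste(bonds$res_i, bonds$res_j)
  for (k in seq_len(length(cys) - 5L)) {
    w <- cys[k:(k + 5L)]
    nested <- c(paste(w[1], w[6]), paste(w[2], w[5]), paste(w[3], w[4]))
    if (all(nested %in% bset)) return(list(start = w[1], end = w[6]))
  }
  NULL
}

#' Detect the NAP1 fold from a canonical topology
#'
#' The NAP1 (nepenthesin-type) fold is a disulfide-stabilised surface-loop
#' insert in the N-terminal subdomain; in the canonical numbering its
#' cysteines carry base labels 4-7 (insertions included). The fold is called
#' present when at least one bond has both ends in that label window.
#'
#' @param topology A \linkS4class{DisulfideTopology}.
#' @return list(start, end, n_bonds, bonds) or NULL when absent.
#' @export
detectNAP1Fold <- function(topology) {
  b <- topology@bonds
  if (nrow(b) == 0L) return(NULL)
  lb <- topology@labels
  inWin <- function(lab) lb$base[match(lab, lb$label)] %in% 4:7
  hit <- inWin(b$label_i) & inWin(b$label_j)
  if (!any(hit)) return(NULL)
  res <- c(b$res_i[hit], b$res_j[hit])
  list(start = min(res), end = max(res), n_bonds = sum(hit),
       bonds = paste0(b$label_i[hit], "-", b$label_j[hit]))
}

#' Detect a C-terminal extension beyond the protease core
#'
#' @param model A \linkS4class{StructureModel}.
#' @param coreEnd Residue index of the last core disulfide-bearing cysteine.
#' @return list(start, end, very_long) when at least 40 residues follow
#'   \code{coreEnd} (\code{very_long} when at least 120), else NULL.
#' @export
detectCExtend <- function(model, coreEnd) {
  n <- max(model@residues$seq_index)
  trailing <- n - coreEnd
  if (trailing < 40L) return(NULL)
  list(start = coreEnd + 1L, end = n, very_long = trailing >= 120L)
}

#' Count beta strands from C-alpha geometry
#'
#' C-alpha-only secondary structure (predicted models carry no hydrogens):
#' a residue is "extended" when its C-alpha(i) to C-alpha(i+2) distance is
#' at least 6.0 A (ideal strand about 6.5 A, ideal helix about 5.5 A); a
#' strand is a run of at least 3 consecutive extended residues. Returns the
#' number of such runs in the given region.
#'
#' @param model A \linkS4class{StructureModel}.
#' @param region Optional c(start, end) residue range (default: whole chain).
#' @param minRun Minimum extended run length (default 3).
#' @return Integer strand count with attribute \code{confident} (FALSE when
#'   fewer than 80% of region residues carry a C-alpha).
#' @export
countInterdomainStrands <- function(model, region = NULL, minRun = 3L) {
  ca <- atomCoords(model, "CA")
  idx <- as.integer(rownames(ca))
  if (!is.null(region)) {
    keep <- idx >= region[1] & idx <= region[2]
    ca <- ca[keep, , drop = FALSE]; idx <- idx[keep]
  }
  nReg <- if (is.null(region)) nResidues(model) else diff(region) + 1L
  confident <- length(idx) >= 0.8 * nReg
  if (length(idx) < minRun + 2L)
    return(structure(0L, confident = confident))
  ## extended test needs consecutive residue triples
  ext <- logical(length(idx))
  for (i in seq_len(length(idx) - 2L)) {
    if (idx[i + 2L] - idx[i] == 2L) {
      d <- sqrt(sum((ca[i + 2L, ] - ca[i, ])^2))
      ext[i] <- d >= 6.0
    }
  }
  r <- rle(ext)
  structure(sum(r$values & r$lengths >= minRun), confident = confident)
}

#' Heuristic signal-peptide and propeptide annotation
#'
#' Prior knowledge (e.g. curated signal peptide/propeptide ranges) can be
#' supplied as \code{annotations} and is passed through untouched. Otherwise
#' a simple heuristic applies: signal peptide = first hydrophobic
#' (TM-like, window 10, mean Kyte-Doolittle >= 1.6) window starting within
#' residues 1-40; propeptide = region between the signal peptide and the
#' first catalytic motif. This is deliberately a heuristic, not a predictor.
#'
#' @param seq Amino-acid string.
#' @param activeSites Result of \code{\link{scanActiveSites}} (optional).
#' @param annotations Optional data.frame(kind, start, end) of curated
#'   segments; returned as-is with heuristic segments only for kinds absent.
#' @return data.frame(kind, start, end).
#' @export
annotateTerminalSegments <- function(seq, activeSites = NULL, annotations = NULL) {
  have <- if (!is.null(annotations)) unique(annotations$kind) else character()
  out <- if (!is.null(annotations))
    annotations[, c("kind", "start", "end"), drop = FALSE]
  else data.frame(kind = character(), start = integer(), end = integer())
  if (!"signal_peptide" %in% have) {
    tm <- detectTMHelix(seq, window = 10L, threshold = 1.6)
    tm <- tm[tm$start <= 40L, , drop = FALSE]
    if (nrow(tm) > 0L)
      out <- rbind(out, data.frame(kind = "signal_peptide", start = 1L,
                                   end = min(tm$end[1L], 40L)))
  }
  if (!"propeptide" %in% have && !is.null(activeSites) &&
      !is.na(activeSites$pos1)) {
    spEnd <- if (any(out$kind == "signal_peptide"))
      max(out$end[out$kind == "signal_peptide"]) else 0L
    if (activeSites$pos1 - 1L > spEnd + 1L)
      out <- rbind(out, data.frame(kind = "propeptide", start = spEnd + 1L,
                                   end = activeSites$pos1 - 1L))
  }
  out
}
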