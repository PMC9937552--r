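#' Detect disulfide bonds geometrically
#'
#' Candidate bonds are cysteine pairs whose SG (sulfur) atoms lie within
#' \code{maxDistance} of each other. The reported bond set is the
#' maximum-cardinality matching over those candidates that, among all
#' maximum-cardinality matchings, minimises the total SG-SG distance; residual
#' ties are broken by the lexicographically smallest (res_i, res_j) bond list.
#' Each cysteine therefore takes part in at most one bond.
#'
#' Bonds in which either residue has pLDDT < 50 are flagged
#' (\code{low_confidence}), not dropped.
#'
#' @param model A \linkS4class{StructureModel}.
#' @param maxDistance Maximum SG-SG distance in Angstrom (default 2.5; the
#'   covalent S-S bond is about 2.05 A, the slack absorbs model error).
#' @return data.frame with columns \code{res_i}, \code{res_j} (residue
#'   seq_index, res_i < res_j), \code{sg_distance}, \code{low_confidence}.
#'   A model without cysteines yields a zero-row frame.
#' @examples
#' s <- synthStructure(synthTopologyTemplate("groupIII_ref"), seed = 7)
#' detectDisulfides(s$model)
#' @export
detectDisulfides <- function(model, maxDistance = 2.5) {
  stopifnot(maxDistance > 0)
  empty <- data.frame(res_i = integer(), res_j = integer(),
                      sg_distance = numeric(), low_confidence = logical())
  res <- model@residues
  cys <- res$seq_index[res$aa == "C"]
  if (length(cys) == 0L) return(empty)
  sg <- atomCoords(model, "SG")
  have <- cys[as.character(cys) %in% rownames(sg)]
  if (length(have) < length(cys))
    warning(length(cys) - length(have), " Cys residue(s) lack an SG atom; skipped",
            call. = FALSE)
  if (length(have) < 2L) return(empty)
  sg <- sg[as.character(have), , drop = FALSE]

  d <- as.matrix(stats::dist(sg))
  idx <- which(upper.tri(d) & d <= maxDistance, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cand <- data.frame(i = idx[, 1], j = idx[, 2], d = d[idx])

  sel <- bestMatching(cand, length(have))
  if (nrow(sel) == 0L) return(empty)
  plddt <- res$plddt[match(have, res$seq_index)]
  out <- data.frame(
    res_i = have[sel$i], res_j = have[sel$j],
    sg_distance = sel$d,
    low_confidence = plddt[sel$i] < 50 | plddt[sel$j] < 50
  )
  out[order(out$res_i), , drop = FALSE]
}

## Exact search for the optimal matching: maximise bond count, then minimise
## total distance, then lexicographically smallest (i, j) list. Cysteine
## counts per chain are small, so exhaustive recursion is fine.
bestMatching <- function(cand, nVert) {
  nbrs <- lapply(seq_len(nVert), function(v) which(cand$i == v | cand$j == v))
  best <- NULL
  bestKey <- NULL
  selKey <- function(rows) {
    sel <- cand[rows, , drop = FALSE]
    ord <- order(sel$i, sel$j)
    list(n = nrow(sel), total = sum(sel$d),
         lex = as.vector(rbind(sel$i[ord], sel$j[ord])))
  }
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$n != b$n) return(a$n > b$n)
    if (abs(a$total - b$total) > 1e-12) return(a$total < b$total)
    la <- a$lex; lb <- b$lex
    for (k in seq_len(min(length(la), length(lb)))) {
      if (la[k] != lb[k]) return(la[k] < lb[k])
    }
    FALSE
  }
  recurse <- function(v, used, rows) {
    while (v <= nVert && (used[v] || length(nbrs[[v]]) == 0L)) v <- v + 1L
    if (v > nVert) {
      key <- selKey(rows)
      if (better(key, bestKey)) {
        best <<- rows; bestKey <<- key
      }
      return(invisible(NULL))
    }
    for (e in nbrs[[v]]) {
      w <- if (cand$i[e] == v) cand$j[e] else cand$i[e]
      if (!used[w] && !used[v]) {
        used[c(v, w)] <- TRUE
        recurse(v + 1L, used, c(rows, e))
        used[c(v, w)] <- FALSE
      }
    }
    recurse(v + 1L, used, rows)  # leave v unmatched
  }
  recurse(1L, logical(nVert), integer(0))
  cand[best, , drop = FALSE]
}

#' Express a query's disulfide bonds in a canonical reference numbering
#'
#' The query sequence is aligned globally (Needleman-Wunsch, BLOSUM62, gap
#' open 10 / extend 0.5 by default) to the reference sequence. A query
#' cysteine aligned to a reference cysteine inherits its base label (C1..CN);
#' any other query cysteine receives the preceding base label plus an
#' insertion letter (a, b, c, ...) in sequence order (e.g. C6a). Reference
#' labels with no query counterpart are reported as lacking.
#'
#' @param querySeq Query amino-acid string.
#' @param queryBonds data.frame of detected bonds as returned by
#'   \code{\link{detectDisulfides}} (residue indices refer to positions in
#'   \code{querySeq}).
#' @param reference A reference numbering as returned by
#'   \code{\link{referenceTopology}}, or one of its identifiers
#'   ("mp4g19220", "ASPR1", "APA1").
#' @param modelId Identifier recorded in the result.
#' @param gapOpening,gapExtension Alignment gap penalties.
#' @return A \linkS4class{DisulfideTopology}.
#' @examples
#' ref <- referenceTopology("ASPR1")
#' top <- canonicalNumbering(ref$seq, referenceBondTable(ref), ref)
#' topologyString(top)
#' @export
canonicalNumbering <- function(querySeq, queryBonds, reference,
                               modelId = "query",
                               gapOpening = 10, gapExtension = 0.5) {
  if (is.character(reference)) reference <- referenceTopology(reference)
  querySeq <- as.character(querySeq)
  if (!nzchar(querySeq)) stop("empty query sequence", call. = FALSE)

  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(querySeq), Biostrings::AAString(reference$seq),
    substitutionMatrix = "BLOSUM62", gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  qa <- aaChars(as.character(Biostrings::alignedPattern(pa)))
  ra <- aaChars(as.character(Biostrings::alignedSubject(pa)))

  qpos <- cumsum(qa != "-")        # query coordinate at each column
  rpos <- cumsum(ra != "-")        # reference coordinate consumed so far
  refAt <- ifelse(ra != "-", rpos, NA_integer_)  # ref residue aligned to column

  qchars <- aaChars(querySeq)
  qcys <- which(qchars == "C")
  refCysPos <- reference$cys$pos
  refCysBase <- reference$cys$base

  base <- integer(length(qcys))
  ins <- character(length(qcys))
  inherited <- logical(length(refCysBase))
  for (k in seq_along(qcys)) {
    col <- match(qcys[k], ifelse(qa != "-", qpos, NA_integer_))
    rp <- refAt[col]
    hit <- if (!is.na(rp)) match(rp, refCysPos) else NA_integer_
    if (!is.na(hit) && ra[col] == "C") {
      base[k] <- refCysBase[hit]
      ins[k] <- ""
      inherited[hit] <- TRUE
    } else {
      ## preceding reference cysteine (by reference coordinate consumed)
      prec <- refCysBase[refCysPos <= rpos[col]]
      base[k] <- if (length(prec)) max(prec) else 0L
      ins[k] <- "?"                # assigned below, in sequence order
    }
  }
  for (b in unique(base[ins == "?"])) {
    w <- which(base == b & ins == "?")
    ins[w] <- letters[seq_along(w)]
  }

  labels <- data.frame(
    seq_index = qcys,
    label = paste0("C", base, ins),
    base = base,
    insertion = ins,
    stringsAsFactors = FALSE
  )
  lacking <- if (any(!inherited)) paste0("C", refCysBase[!inherited]) else character(0)

  if (is.null(queryBonds) || nrow(queryBonds) == 0L) {
    bonds <- data.frame(res_i = integer(), res_j = integer(),
                        label_i = character(), label_j = character(),
                        sg_distance = numeric(), flagged = logical())
  } else {
    li <- labels$label[match(queryBonds$res_i, labels$seq_index)]
    lj <- labels$label[match(queryBonds$res_j, labels$seq_index)]
    if (anyNA(li) || anyNA(lj))
      stop("queryBonds refer to residues that are not Cys in querySeq",
           call. = FALSE)
    bonds <- data.frame(
      res_i = queryBonds$res_i, res_j = queryBonds$res_j,
      label_i = li, label_j = lj,
      sg_distance = if ("sg_distance" %in% names(queryBonds))
        queryBonds$sg_distance else NA_real_,
      flagged = if ("low_confidence" %in% names(queryBonds))
        queryBonds$low_confidence else FALSE,
      stringsAsFactors = FALSE
    )
  }
  new("DisulfideTopology",
      model_id = modelId, reference_id = reference$id,
      labels = labels, bonds = bonds, lacking = lacking)
}

## Sort key for canonical labels: base, then insertion ("" before "a" < "b").
labelKey <- function(base, insertion) {
  base * 100 + ifelse(insertion == "", 0, match(insertion, letters))
}

#' @rdname topologyString
#' @export
setMethod("topologyString", "DisulfideTopology", function(topology) {
  b <- topology@bonds
  lb <- topology@labels
  keyOf <- function(lab) {
    i <- match(lab, lb$label)
    labelKey(lb$base[i], lb$insertion[i])
  }
  if (nrow(b) == 0L) {
    bondStr <- "∅"
  } else {
    ki <- keyOf(b$label_i); kj <- keyOf(b$label_j)
    swap <- ki > kj
    l1 <- ifelse(swap, b$label_j, b$label_i)
    l2 <- ifelse(swap, b$label_i, b$label_j)
    k1 <- pmin(ki, kj); k2 <- pmax(ki, kj)
    ord <- order(k1, k2)
    bondStr <- paste(paste0(l1[ord], "-", l2[ord]), collapse = ";")
  }
  lackStr <- if (length(topology@lacking)) {
    lk <- as.integer(sub("^C([0-9]+).*$", "\\1", topology@lacking))
    paste(topology@lacking[order(lk)], collapse = ",")
  } else "-"
  extra <- lb$label[lb$insertion != ""]
  extraStr <- if (length(extra)) paste(extra, collapse = ",") else "-"
  paste0(bondStr, "|lacking:", lackStr, "|extra:", extraStr)
})

#' Bond table of a reference numbering, in query coordinates
#'
#' Convenience for tests and self-mapping: turns the label-pair bond list of
#' a \code{\link{referenceTopology}} into a residue-index bond table.
#'
#' @param reference A reference numbering list.
#' @return data.frame with res_i, res_j, sg_distance (NA).
#' @export
referenceBondTable <- function(reference) {
  if (is.character(reference)) reference <- referenceTopology(reference)
  pos <- setNames(reference$cys$pos, paste0("C", reference$cys$base))
  res_i <- pos[vapply(reference$bonds, `[`, character(1), 1L)]
  res_j <- pos[vapply(reference$bonds, `[`, character(1), 2L)]
  swap <- res_i > res_j
  tmp <- res_i[swap]; res_i[swap] <- res_j[swap]; res_j[swap] <- tmp
  out <- data.frame(res_i = unname(res_i), res_j = unname(res_j),
                    sg_distance = NA_real_)
  out[order(out$res_i), , drop = FALSE]
}
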