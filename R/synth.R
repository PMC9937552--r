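## Synthetic-data generator. Everything downstream (disulfide detection,
## canonical numbering, domain annotation, trees, intron statistics, the rule
## engine) is exercised against fixtures built here with known ground truth,
## so the whole pipeline is testable without any downloads. Geometry is
## idealized, not physically relaxed: downstream operations consume distances
## and segment patterns only.

## Evaluate expr under a fixed RNG seed without disturbing the caller's state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic background sequence: no cysteines (those are planted), and
## no D-x-G tripeptides (so active-site motifs occur only where planted).
backgroundSeq <- function(n, seed) {
  withSeed(seed, {
    alpha <- setdiff(AA_ALPHABET, "C")
    freq <- ROBINSON_BACKGROUND[alpha]
    s <- sample(alpha, n, replace = TRUE, prob = freq / sum(freq))
    repeat {
      hit <- regexpr("D.G", paste(s, collapse = ""))
      if (hit < 0) break
      s[hit] <- "E"
    }
    s
  })
}

## Shared protease-core layout (coordinates within the 450-residue core).
## Two catalytic tetrads; 12 cysteines C1..C12 wired as in the canonical
## group II/III topology; insertion-coded positions used by the variant
## templates.
CORE_LEN <- 450L
CORE_MOTIF1_POS <- 95L
CORE_MOTIF2_POS <- 310L
CORE_CYS <- c(C1 = 120L, C2 = 124L, C3 = 127L, C4 = 150L, C5 = 155L,
              C6 = 163L, C7 = 170L, C8 = 205L, C9 = 340L, C10 = 370L,
              C11 = 395L, C12 = 425L)
CORE_INS <- c(C5a = 158L, C5b = 160L, C6a = 165L, C6b = 167L,
              C9a = 350L, C11a = 405L)
CORE_BONDS <- list(c("C1", "C8"), c("C2", "C3"), c("C4", "C6"),
                   c("C5", "C7"), c("C9", "C12"), c("C10", "C11"))

## APA1-like (group I) layout: its own C1..C12 numbering, a saposin-like
## insert (nested disulfide triple) between the second catalytic motif and
## the C-terminal core bond.
GI_LEN <- 470L
GI_CYS <- c(C1 = 113L, C2 = 119L, C3 = 278L, C4 = 282L, C5 = 317L,
            C6 = 342L, C7 = 348L, C8 = 380L, C9 = 383L, C10 = 411L,
            C11 = 425L, C12 = 462L)
GI_BONDS <- list(c("C1", "C2"), c("C3", "C4"), c("C5", "C10"),
                 c("C6", "C9"), c("C7", "C8"), c("C11", "C12"))
GI_SAPOSIN <- c(312L, 417L)

#' Topology templates for the synthetic generator
#'
#' Each template describes one subgroup-typical architecture: cysteine
#' positions with canonical labels, the disulfide wiring, catalytic motifs
#' (canonical DTGS/DSGT, or DLGG/SSVN for the group-IV template), and
#' optional prosegment / C-terminal extension / saposin-like insert.
#'
#' @param name One of "groupI_A", "groupI_B", "groupII_ref", "groupII_APCB1",
#'   "groupII_B", "groupII_C", "groupII_D", "groupIII_ref", "groupIII_A",
#'   "groupIII_CD", "groupIII_F", "groupIII_G_var", "groupIV".
#' @return A template list (fields: name, group, subgroup, length, motifs,
#'   cys, bonds, prefix_len, ext_len, saposin, tm, annotations).
#' @export
synthTopologyTemplate <- function(name) {
  coreTpl <- function(name, group, subgroup, drop = character(), add = character(),
                      bonds = CORE_BONDS, prefix = 0L, ext = 0L,
                      motifs = c("DTGS", "DSGT"), extCys = integer(),
                      tm = NULL, annotations = character()) {
    cys <- c(CORE_CYS[setdiff(names(CORE_CYS), drop)], CORE_INS[add])
    cys <- sort(cys) + prefix
    extCysAbs <- if (length(extCys)) prefix + CORE_LEN + extCys else integer()
    names(extCysAbs) <- if (length(extCys)) paste0("C12", letters[seq_along(extCys)])
    cys <- c(cys, extCysAbs)
    list(name = name, group = group, subgroup = subgroup,
         length = prefix + CORE_LEN + ext,
         motif1 = c(pos = CORE_MOTIF1_POS + prefix, str = motifs[1]),
         motif2 = c(pos = CORE_MOTIF2_POS + prefix, str = motifs[2]),
         cys = cys, bonds = bonds,
         prefix_len = prefix, ext_len = ext,
         saposin = NULL, tm = tm, annotations = annotations,
         scaffold = "core")
  }
  dropBond <- function(b, pair) Filter(function(x) !setequal(x, pair), b)

  switch(name,
    groupII_ref = coreTpl(name, "II", "II-A"),
    groupIII_ref = coreTpl(name, "III", "III-B"),
    groupII_APCB1 = coreTpl(name, "II", "II-A", drop = "C4", add = "C6a",
      bonds = c(dropBond(CORE_BONDS, c("C4", "C6")), list(c("C6", "C6a"))),
      prefix = 80L, tm = c(30L, 52L)),
    groupII_B = coreTpl(name, "II", "II-B", ext = 60L),
    groupII_C = coreTpl(name, "II", "II-C", ext = 160L, extCys = c(60L, 70L),
      bonds = c(CORE_BONDS, list(c("C12a", "C12b")))),
    groupII_D = coreTpl(name, "II", "II-D", annotations = "GPI"),
    groupIII_A = coreTpl(name, "III", "III-A", add = c("C6a", "C6b"),
      bonds = c(CORE_BONDS, list(c("C6a", "C6b")))),
    groupIII_CD = coreTpl(name, "III", "III-C|III-D", drop = c("C2", "C3"),
      bonds = dropBond(CORE_BONDS, c("C2", "C3"))),
    groupIII_F = coreTpl(name, "III", "III-F",
      bonds = dropBond(CORE_BONDS, c("C4", "C6"))),
    groupIII_G_var = coreTpl(name, "III", "III-G", drop = c("C4", "C5"),
      add = c("C9a", "C11a"),
      bonds = c(dropBond(dropBond(CORE_BONDS, c("C4", "C6")), c("C5", "C7")),
                list(c("C6", "C7"), c("C9a", "C11a")))),
    groupIV = coreTpl(name, "IV", "IV", drop = c("C2", "C3"), add = c("C5a", "C5b"),
      bonds = c(dropBond(CORE_BONDS, c("C2", "C3")), list(c("C5a", "C5b"))),
      motifs = c("DLGG", "SSVN")),
    groupI_A = list(name = name, group = "I", subgroup = "I-A",
      length = GI_LEN,
      motif1 = c(pos = 95L, str = "DTGS"), motif2 = c(pos = 265L, str = "DSGT"),
      cys = GI_CYS, bonds = GI_BONDS,
      prefix_len = 0L, ext_len = 0L, saposin = GI_SAPOSIN, tm = NULL,
      annotations = character(), scaffold = "groupI"),
    groupI_B = local({
      del <- GI_SAPOSIN[2] - GI_SAPOSIN[1] + 1L
      keep <- GI_CYS[GI_CYS < GI_SAPOSIN[1] | GI_CYS > GI_SAPOSIN[2]]
      keep[keep > GI_SAPOSIN[2]] <- keep[keep > GI_SAPOSIN[2]] - del
      list(name = name, group = "I", subgroup = "I-B",
           length = GI_LEN - del,
           motif1 = c(pos = 95L, str = "DTGS"), motif2 = c(pos = 265L, str = "DSGT"),
           cys = keep,
           bonds = list(c("C1", "C2"), c("C3", "C4"), c("C11", "C12")),
           prefix_len = 0L, ext_len = 0L, saposin = NULL, tm = NULL,
           annotations = character(), scaffold = "groupI")
    }),
    stop("unknown template: ", name, call. = FALSE)
  )
}

## Template sequence: deterministic shared scaffold + planted features, so
## that homologous templates align cleanly (as real family members would).
synthTemplateSequence <- function(template) {
  core <- backgroundSeq(CORE_LEN, 7919L)
  gI <- backgroundSeq(GI_LEN, 7927L)
  s <- switch(template$scaffold,
    core = {
      pre <- if (template$prefix_len > 0L) {
        p <- backgroundSeq(template$prefix_len, 7933L)
        if (!is.null(template$tm))  # plant a hydrophobic TM stretch
          p[template$tm[1]:template$tm[2]] <-
            rep(c("L", "I", "V", "F", "L", "A"),
                length.out = template$tm[2] - template$tm[1] + 1L)
        p
      } else character()
      ext <- if (template$ext_len > 0L) backgroundSeq(template$ext_len, 7937L +
                                                        template$ext_len) else character()
      c(pre, core, ext)
    },
    groupI = {
      g <- gI
      if (is.null(template$saposin)) {  # groupI_B: saposin insert deleted
        g <- g[-(GI_SAPOSIN[1]:GI_SAPOSIN[2])]
      }
      g
    })
  m1 <- as.integer(template$motif1["pos"]); s1 <- template$motif1["str"]
  m2 <- as.integer(template$motif2["pos"]); s2 <- template$motif2["str"]
  s[m1:(m1 + 3L)] <- aaChars(s1)
  s[m2:(m2 + 3L)] <- aaChars(s2)
  s[template$cys] <- "C"
  paste(s, collapse = "")
}

#' Generate an idealized structure with planted disulfide bonds
#'
#' C-alpha atoms are laid out along a wide spiral (3.8 A consecutive spacing,
#' non-neighbours well separated). For every planted bond the two SG atoms
#' are placed on the radial ray of the first residue exactly 2.05 A apart
#' (the covalent S-S length); unbonded cysteines get an SG 1.8 A outward.
#' Gaussian jitter with RMS per-atom displacement \code{jitterSigma}
#' (per-component sd \code{jitterSigma/sqrt(3)}) is then applied to every
#' atom.
#'
#' @param template A template from \code{\link{synthTopologyTemplate}} (or its
#'   name).
#' @param jitterSigma RMS coordinate displacement per atom, in Angstrom.
#' @param seed Integer seed; same seed, same output, byte for byte.
#' @param plddt Constant per-residue confidence recorded in the model.
#' @return list(model = \linkS4class{StructureModel}, truth = list(bonds,
#'   cys_labels, motifs, saposin, tm, template)).
#' @export
synthStructure <- function(template, jitterSigma = 0, seed = 1L, plddt = 90) {
  if (is.character(template)) template <- synthTopologyTemplate(template)
  stopifnot(jitterSigma >= 0)
  seqstr <- synthTemplateSequence(template)
  n <- nchar(seqstr)
  k <- seq_len(n)
  theta <- k * 0.09
  R0 <- 40
  ca <- cbind(R0 * cos(theta), R0 * sin(theta), k * 1.2)
  radial <- cbind(cos(theta), sin(theta), 0)

  cysPos <- template$cys
  bondPos <- lapply(template$bonds, function(b) sort(unname(cysPos[b])))
  for (b in bondPos) if (any(duplicated(unlist(bondPos))))
    stop("infeasible template: a cysteine appears in two bonds", call. = FALSE)

  sgOf <- setNames(rep(NA_real_, length(cysPos)), cysPos)
  sg <- matrix(NA_real_, nrow = length(cysPos), ncol = 3)
  rownames(sg) <- as.character(sort(unname(cysPos)))
  place <- function(i, dist) ca[i, ] + dist * radial[i, ]
  bonded <- unlist(bondPos)
  for (b in bondPos) {
    sg[as.character(b[1]), ] <- place(b[1], 1.8)
    sg[as.character(b[2]), ] <- place(b[1], 1.8 + 2.05)
  }
  for (p in setdiff(sort(unname(cysPos)), bonded))
    sg[as.character(p), ] <- place(p, 1.8)

  atoms <- data.frame(
    seq_index = c(k, as.integer(rownames(sg))),
    name = c(rep("CA", n), rep("SG", nrow(sg))),
    element = c(rep("C", n), rep("S", nrow(sg))),
    x = c(ca[, 1], sg[, 1]), y = c(ca[, 2], sg[, 2]), z = c(ca[, 3], sg[, 3]),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[order(atoms$seq_index, atoms$name), , drop = FALSE]
  if (jitterSigma > 0) {
    jit <- withSeed(seed, matrix(rnorm(3L * nrow(atoms), sd = jitterSigma / sqrt(3)),
                                 ncol = 3))
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] + jit
  }
  model <- new("StructureModel",
    id = paste0("synth_", template$name, "_s", seed),
    residues = data.frame(seq_index = k, aa = aaChars(seqstr), plddt = plddt,
                          stringsAsFactors = FALSE),
    atoms = atoms, source = "synthetic")
  truthBonds <- do.call(rbind, lapply(bondPos, function(b)
    data.frame(res_i = b[1], res_j = b[2])))
  if (is.null(truthBonds))
    truthBonds <- data.frame(res_i = integer(), res_j = integer())
  truthBonds <- truthBonds[order(truthBonds$res_i), , drop = FALSE]
  list(model = model,
       truth = list(bonds = truthBonds,
                    cys_labels = cysPos,
                    motif1 = template$motif1, motif2 = template$motif2,
                    saposin = template$saposin, tm = template$tm,
                    template = template$name))
}

#' Generate an idealized multi-strand beta-sheet model
#'
#' Strands are extended zigzags (consecutive C-alpha rise 3.3 A, alternating
#' 1 A lateral offset, so the i to i+2 distance is about 6.6 A); strands are
#' stacked 4.8 A apart and connected by compact 3-residue turns.
#'
#' @param nStrands Number of strands (>= 0).
#' @param strandLen Residues per strand.
#' @param seed Seed (used only for the residue identities).
#' @return A \linkS4class{StructureModel}.
#' @export
synthSheetStructure <- function(nStrands, strandLen = 7L, seed = 1L) {
  coords <- NULL
  for (s in seq_len(nStrands)) {
    i <- seq_len(strandLen)
    x <- if (s %% 2L == 1L) i * 3.3 else (strandLen - i + 1L) * 3.3
    strand <- cbind(x, ((i %% 2L) - 0.5) * 2, s * 4.8)
    coords <- rbind(coords, strand)
    if (s < nStrands) {
      xend <- strand[strandLen, 1]
      turn <- cbind(xend + c(1.5, 2.2, 1.5) * ifelse(s %% 2L == 1L, 1, -1),
                    c(0.8, 0, -0.8), s * 4.8 + c(1.2, 2.4, 3.6))
      coords <- rbind(coords, turn)
    }
  }
  if (is.null(coords)) coords <- matrix(numeric(), ncol = 3)
  n <- nrow(coords)
  if (n == 0L) stop("nStrands must be >= 1 for a non-empty model", call. = FALSE)
  aa <- withSeed(seed, sample(setdiff(AA_ALPHABET, "C"), n, replace = TRUE))
  new("StructureModel",
      id = paste0("synth_sheet", nStrands),
      residues = data.frame(seq_index = seq_len(n), aa = aa, plddt = 90,
                            stringsAsFactors = FALSE),
      atoms = data.frame(seq_index = seq_len(n), name = "CA", element = "C",
                         x = coords[, 1], y = coords[, 2], z = coords[, 3],
                         stringsAsFactors = FALSE),
      source = "synthetic")
}

#' Generate an idealized all-helix model
#'
#' Standard alpha-helix internal coordinates: radius 2.3 A, 100 degrees per
#' residue, 1.5 A rise (i to i+2 C-alpha distance about 5.5 A, below the
#' extended-strand range).
#'
#' @param n Number of residues.
#' @param seed Seed for residue identities.
#' @return A \linkS4class{StructureModel}.
#' @export
synthHelixStructure <- function(n = 30L, seed = 1L) {
  k <- seq_len(n)
  th <- k * (100 * pi / 180)
  coords <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * k)
  aa <- withSeed(seed, sample(setdiff(AA_ALPHABET, "C"), n, replace = TRUE))
  new("StructureModel",
      id = "synth_helix",
      residues = data.frame(seq_index = k, aa = aa, plddt = 90,
                            stringsAsFactors = FALSE),
      atoms = data.frame(seq_index = k, name = "CA", element = "C",
                         x = coords[, 1], y = coords[, 2], z = coords[, 3],
                         stringsAsFactors = FALSE),
      source = "synthetic")
}

## Default group proportions: the census proportions of the four groups in
## the 12-species family survey (90/275/682/153 of 1200).
SYNTH_GROUP_PROPORTIONS <- c(I = 90, II = 275, III = 682, IV = 153) / 1200

#' Simulate a protein family along a known 4-group tree
#'
#' Four clades are grown (one per group), joined by long stems, and
#' sequences are evolved from a shared protease-core root under a
#' single-rate Jukes-Cantor-style amino-acid model (each site on a branch of
#' length t mutates with probability 1 - exp(-rate * t) to a uniformly drawn
#' different residue). Catalytic-motif and cysteine positions are held fixed
#' (planted features): groups I-III carry DTGS/DSGT, the group-IV lineage
#' carries DLGG/SSVN. Sequences contain no indels, so the returned set is an
#' aligned FASTA-ready MSA of width 450.
#'
#' @param nLeaves Total number of genes (>= 4).
#' @param seed Integer seed; fully deterministic.
#' @param proportions Named group proportions (I, II, III, IV); defaults to
#'   the family-census proportions.
#' @param rate Substitution rate multiplier.
#' @param stem Stem branch length isolating each group clade.
#' @return list(alignment = named character vector (equal widths),
#'   tree = true phylo, groups = named group labels, anchors = one anchor
#'   leaf per group).
#' @export
synthFamily <- function(nLeaves = 200L, seed = 42L,
                        proportions = SYNTH_GROUP_PROPORTIONS,
                        rate = 1, stem = 0.45) {
  stopifnot(nLeaves >= 4L)
  proportions <- proportions / sum(proportions)
  nPer <- setNames(pmax(1L, round(nLeaves * proportions)), names(proportions))
  while (sum(nPer) > nLeaves) nPer[which.max(nPer)] <- nPer[which.max(nPer)] - 1L
  while (sum(nPer) < nLeaves) nPer[which.max(proportions)] <-
    nPer[which.max(proportions)] + 1L

  groupsOrder <- c("I", "II", "III", "IV")
  subtrees <- lapply(seq_along(groupsOrder), function(gi) {
    g <- groupsOrder[gi]
    n <- nPer[g]
    withSeed(childSeed(seed, gi), {
      tr <- if (n >= 2L) ape::rtree(n) else
        structure(list(edge = matrix(c(2L, 1L), 1L), tip.label = "t1",
                       edge.length = 0.05, Nnode = 1L), class = "phylo")
      tr$edge.length <- 0.02 + 0.10 * tr$edge.length / max(tr$edge.length, 1e-9)
      tr$tip.label <- sprintf("g%s_%03d", g, seq_len(n))
      tr
    })
  })
  nwk <- vapply(subtrees, function(tr) sub(";$", "", ape::write.tree(tr)),
                character(1))
  tree <- ape::read.tree(text = sprintf("((%s:%g,%s:%g):0.05,(%s:%g,%s:%g):0.05);",
    nwk[1], stem, nwk[2], stem, nwk[3], stem, nwk[4], stem))

  groups <- setNames(sub("^g(I+V?|IV)_.*$", "\\1", tree$tip.label), tree$tip.label)

  ## root sequence: shared protease core with canonical motifs + cysteines
  root <- aaChars(synthTemplateSequence(synthTopologyTemplate("groupII_ref")))
  protected <- c(CORE_MOTIF1_POS:(CORE_MOTIF1_POS + 3L),
                 CORE_MOTIF2_POS:(CORE_MOTIF2_POS + 3L),
                 unname(CORE_CYS))
  L <- length(root)
  nTips <- length(tree$tip.label)
  seqs <- vector("list", nTips + tree$Nnode)
  seqs[[nTips + 1L]] <- root
  edgeOrd <- ape::reorder.phylo(tree, "postorder")$edge
  edgeOrd <- edgeOrd[rev(seq_len(nrow(edgeOrd))), , drop = FALSE]  # preorder
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  elen <- elen[rev(seq_along(elen))]
  withSeed(childSeed(seed, 99L), {
    for (e in seq_len(nrow(edgeOrd))) {
      par <- edgeOrd[e, 1L]; chd <- edgeOrd[e, 2L]
      s <- seqs[[par]]
      p <- 1 - exp(-rate * elen[e])
      mut <- which(runif(L) < p)
      mut <- setdiff(mut, protected)
      if (length(mut)) {
        s[mut] <- vapply(s[mut], function(a)
          sample(setdiff(setdiff(AA_ALPHABET, "C"), a), 1L), character(1))
      }
      seqs[[chd]] <- s
    }
  })
  aln <- vapply(seq_len(nTips), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  names(aln) <- tree$tip.label
  ## plant the group-IV non-canonical motifs
  iv <- groups == "IV"
  if (any(iv)) {
    aln[iv] <- vapply(aln[iv], function(s) {
      ch <- aaChars(s)
      ch[CORE_MOTIF1_POS:(CORE_MOTIF1_POS + 3L)] <- aaChars("DLGG")
      ch[CORE_MOTIF2_POS:(CORE_MOTIF2_POS + 3L)] <- aaChars("SSVN")
      paste(ch, collapse = "")
    }, character(1))
  }
  anchors <- vapply(groupsOrder, function(g) names(groups)[groups == g][1L],
                    character(1))
  list(alignment = aln, tree = tree, groups = groups,
       anchors = setNames(groupsOrder, anchors))
}

## Per-group intron-count pools used by the default synthetic study: intron
## rich in groups I/II, intron poor in III/IV, mirroring the family's
## conserved exon-intron contrast.
SYNTH_INTRON_POOLS <- list(
  I = c(9L, 10L, 10L, 11L, 12L),
  II = c(7L, 8L, 8L, 9L, 10L),
  III = c(0L, 0L, 0L, 1L, 1L),
  IV = c(0L, 0L, 0L, 0L, 1L)
)

#' Generate a GFF3 gene-model file with known exon counts
#'
#' @param plan data.frame with columns \code{gene_id}, \code{n_exons} and
#'   optionally \code{group} and \code{strand}; one transcript per gene.
#' @param seed Seed for exon/intron lengths.
#' @return list(text = character vector of GFF3 lines, truth = the plan with
#'   an added \code{n_introns} column).
#' @export
synthGFF <- function(plan, seed = 1L) {
  header <- "##gff-version 3"
  if (nrow(plan) == 0L)
    return(list(text = header, truth = cbind(plan, n_introns = integer(0))))
  stopifnot(all(plan$n_exons >= 1L))
  if (is.null(plan$strand)) plan$strand <- "+"
  lines <- header
  cursor <- 1000L
  withSeed(seed, {
    for (g in seq_len(nrow(plan))) {
      ne <- plan$n_exons[g]
      exLen <- sample(100:300, ne, replace = TRUE)
      inLen <- if (ne > 1L) sample(80:400, ne - 1L, replace = TRUE) else integer()
      starts <- cursor + c(0L, cumsum(exLen[-ne] + inLen))
      ends <- starts + exLen - 1L
      gid <- plan$gene_id[g]
      tid <- paste0(gid, ".1")
      st <- plan$strand[g]
      lines <- c(lines,
        sprintf("chr1\tapclass_synth\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                starts[1L], ends[ne], st, gid),
        sprintf("chr1\tapclass_synth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                starts[1L], ends[ne], st, tid, gid),
        sprintf("chr1\tapclass_synth\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                starts, ends, st, tid))
      cursor <- ends[ne] + 2000L
    }
  })
  truth <- plan
  truth$n_introns <- plan$n_exons - 1L
  list(text = lines, truth = truth)
}

#' Generate the full synthetic study bundle
#'
#' One call produces everything the end-to-end pipeline consumes: an aligned
#' family with its true tree and group labels, per-gene gene models (intron
#' counts drawn from group-typical pools), and per-gene structure templates
#' (subgroup-typical architectures drawn within each group).
#'
#' @param nGenes Number of genes.
#' @param seed Integer seed.
#' @param jitterSigma Coordinate jitter passed to structure generation.
#' @return list(family, gff, templates (named template names per gene),
#'   intron_truth (named integer), plan).
#' @export
synthBundle <- function(nGenes = 200L, seed = 42L, jitterSigma = 0.2) {
  fam <- synthFamily(nLeaves = nGenes, seed = seed)
  groups <- fam$groups
  tplPool <- list(
    I = c("groupI_A", "groupI_A", "groupI_B"),
    II = c("groupII_APCB1", "groupII_B", "groupII_C", "groupII_D"),
    III = c("groupIII_ref", "groupIII_A", "groupIII_CD", "groupIII_F",
            "groupIII_G_var"),
    IV = "groupIV"
  )
  ids <- names(groups)
  templates <- withSeed(childSeed(seed, 7L), vapply(ids, function(id) {
    pool <- tplPool[[groups[id]]]
    pool[sample.int(length(pool), 1L)]
  }, character(1)))
  introns <- withSeed(childSeed(seed, 8L), vapply(ids, function(id) {
    pool <- SYNTH_INTRON_POOLS[[groups[id]]]
    pool[sample.int(length(pool), 1L)]
  }, integer(1)))
  plan <- data.frame(gene_id = ids, n_exons = introns + 1L,
                     group = unname(groups), stringsAsFactors = FALSE)
  gff <- synthGFF(plan, seed = childSeed(seed, 9L))
  list(family = fam, gff = gff, templates = templates,
       intron_truth = setNames(introns, ids), plan = plan,
       jitterSigma = jitterSigma, seed = seed)
}
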