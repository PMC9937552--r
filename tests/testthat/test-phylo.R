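test_that("column entropy matches closed forms", {
  expect_equal(as.numeric(columnEntropy(c("A", "A", "A", "A"), 1)), 0)
  twenty <- vapply(AA_ALPHABET_TEST, function(a) a, character(1))
  expect_equal(as.numeric(columnEntropy(twenty, 1)), 1)
  # column A,A,C,D: p = (0.5, 0.25, 0.25)
  h <- -sum(c(0.5, 0.25, 0.25) * log2(c(0.5, 0.25, 0.25))) / log2(20)
  expect_equal(as.numeric(columnEntropy(c("A", "A", "C", "D"), 1)), h)
  # all-gap column is removable by definition
  e <- columnEntropy(c("-", "-", "-"), 1)
  expect_equal(as.numeric(e), 1)
  expect_equal(attr(e, "gap_fraction"), 1)
})

test_that("entropy trimming equals the per-column oracle on random alignments", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      nseq <- sample(4:8, 1); width <- 60
      msa <- vapply(seq_len(nseq), function(i)
        paste(sample(c(AA_ALPHABET_TEST, "-"), width, TRUE,
                     prob = c(rep(0.85 / 20, 20), 0.15)), collapse = ""),
        character(1))
      names(msa) <- paste0("s", seq_len(nseq))
      cutoff <- runif(1, 0.7, 0.9)
      tr <- entropyTrim(msa, cutoff, maxGapFraction = 0.4)
      oracle <- which(vapply(seq_len(width), function(j) {
        e <- columnEntropy(msa, j)
        as.numeric(e) <= cutoff && attr(e, "gap_fraction") <= 0.4
      }, logical(1)))
      expect_equal(keptColumns(tr), oracle)
    }
  })
})

test_that("trimming boundary cases behave as specified", {
  conserved <- c(a = "AAAA", b = "AAAA", c = "AAAA")
  tr <- entropyTrim(conserved, 0.7)
  expect_equal(keptColumns(tr), 1:4)
  # cutoff 0: only zero-entropy columns survive
  mix <- c(a = "AC", b = "AD", c = "AE")
  tr0 <- entropyTrim(mix, 0)
  expect_equal(keptColumns(tr0), 1L)
  # keep-everything settings keep every column; trimming is idempotent
  msa <- c(a = "AC-D", b = "ACAD", c = "GCAD")
  trAll <- entropyTrim(msa, 1.0, 1.0)
  expect_equal(keptColumns(trAll), 1:4)
  tr1 <- entropyTrim(msa, 0.8, 0.5)
  tr2 <- entropyTrim(tr1@sequences, 0.8, 0.5)
  expect_equal(tr2@sequences, tr1@sequences)
  expect_error(entropyTrim(c(a = "--", b = "--", c = "--"), 0.8), "trimmed")
})

test_that("distances match direct counting, with Poisson correction", {
  msa <- c(a = "AAAA", b = "AAAT", c = "AATT")
  d <- distanceMatrix(msa)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0.5)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  dp <- distanceMatrix(msa, model = "poisson")
  expect_equal(dp["a", "b"], -log(1 - 0.25))
  # identical sequences -> zero matrix
  z <- distanceMatrix(c(a = "AC", b = "AC", c = "AC"))
  expect_true(all(z == 0))
  # random alignments agree with brute-force per-pair recounting
  withr::with_seed(17, {
    msa2 <- vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "-"), 30, TRUE), collapse = ""), character(1))
    names(msa2) <- letters[1:4]
    d2 <- distanceMatrix(msa2)
    ch <- strsplit(msa2, "")
    for (i in 1:3) for (j in (i + 1):4) {
      ok <- ch[[i]] != "-" & ch[[j]] != "-"
      expect_equal(d2[i, j], mean(ch[[i]][ok] != ch[[j]][ok]))
    }
  })
})

test_that("NJ recovers an additive 4-taxon tree exactly", {
  # tree: ((a:2,b:3):1,(c:4,d:5)); pairwise path lengths are additive
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 5
  d["a", "c"] <- d["c", "a"] <- 7
  d["a", "d"] <- d["d", "a"] <- 8
  d["b", "c"] <- d["c", "b"] <- 8
  d["b", "d"] <- d["d", "b"] <- 9
  d["c", "d"] <- d["d", "c"] <- 9
  tr <- njTree(d)
  expect_true(ape::is.monophyletic(ape::root(tr, "d"), c("a", "b")))
  # branch lengths reproduce the generating tree
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[letters[1:4], letters[1:4]], d, tolerance = 1e-9)
})

test_that("NJ topology recovery holds over 100 random additive 8-taxon matrices", {
  withr::with_seed(19, {
    ok <- vapply(1:100, function(rep) {
      true <- ape::rtree(8)
      true$edge.length <- runif(nrow(true$edge), 0.2, 1.5)
      d <- ape::cophenetic.phylo(true)
      est <- njTree(d[true$tip.label, true$tip.label])
      ape::dist.topo(ape::unroot(true), ape::unroot(est)) == 0
    }, logical(1))
    expect_equal(mean(ok), 1)
  })
})

test_that("n = 3 gives the closed-form three-point branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- njTree(d)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["x"]], (3 + 4 - 5) / 2)
  expect_equal(el[["y"]], (3 + 5 - 4) / 2)
  expect_equal(el[["z"]], (4 + 5 - 3) / 2)
  bad <- d; bad[1, 2] <- NaN
  expect_error(njTree(bad), "NA|NaN")
})

test_that("bootstrap supports separate simulated clades strongly", {
  fam <- synthFamily(16, seed = 42)
  trm <- entropyTrim(fam$alignment, 1.0, 1.0)
  tr <- bootstrapSupports(trm, nReplicates = 50, seed = 42)
  # the edge separating group I+II from III+IV (or any group stem) must be
  # strongly supported; check the best-supported internal edge
  expect_gte(max(tr$node.label, na.rm = TRUE), 0.95)
  # single replicate -> supports in {0, 1}
  tr1 <- bootstrapSupports(trm, nReplicates = 1, seed = 1)
  expect_true(all(tr1$node.label %in% c(0, 1)))
})

test_that("Newick write -> read -> write round-trips byte-identically", {
  fam <- synthFamily(12, seed = 2)
  s1 <- ape::write.tree(fam$tree)
  t2 <- ape::read.tree(text = s1)
  expect_identical(ape::write.tree(t2), s1)
})

test_that("clade assignment labels simulated families accurately", {
  fam <- synthFamily(50, seed = 42)
  tr <- njTree(distanceMatrix(entropyTrim(fam$alignment)))
  cl <- cladeAssign(tr, fam$anchors)
  nonAnchor <- setdiff(names(cl), names(fam$anchors))
  expect_gte(mean(cl[nonAnchor] == fam$groups[nonAnchor]), 0.95)
  expect_error(cladeAssign(tr, c(nosuchleaf = "I")), "not in tree")
})

test_that("a leaf between two anchor clades is unassigned", {
  # constructed degenerate tree: the orphan's first anchor-containing
  # ancestor holds anchors of both groups
  tr <- ape::read.tree(text = "((a1:1,b1:1):1,orphan:1.2);")
  cl <- cladeAssign(tr, c(a1 = "A", b1 = "B"))
  expect_equal(unname(cl["orphan"]), "unassigned")
})
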