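cysModel <- function(sg, plddt = 90) {
  # model of n Cys residues with given SG coordinates (CA colocated nearby)
  n <- nrow(sg)
  new("StructureModel", id = "cysfix",
      residues = data.frame(seq_index = 1:n, aa = "C", plddt = plddt),
      atoms = rbind(
        data.frame(seq_index = 1:n, name = "CA", element = "C",
                   x = sg[, 1] + 1.5, y = sg[, 2], z = sg[, 3]),
        data.frame(seq_index = 1:n, name = "SG", element = "S",
                   x = sg[, 1], y = sg[, 2], z = sg[, 3])),
      source = "synthetic")
}

test_that("two Cys 2.05 A apart give exactly one bond", {
  m <- cysModel(rbind(c(0, 0, 0), c(2.05, 0, 0)))
  b <- detectDisulfides(m)
  expect_equal(nrow(b), 1L)
  expect_equal(b$res_i, 1L)
  expect_equal(b$sg_distance, 2.05, tolerance = 1e-12)
})

test_that("three mutually close Cys pair the two closest, third stays unpaired", {
  # d12 = 2.0, d13 = 2.3, d23 ~ 2.4: max cardinality is 1 bond; min total
  # distance picks (1,2)
  sg <- rbind(c(0, 0, 0), c(2.0, 0, 0), c(-1.15, 1.99, 0))
  m <- cysModel(sg)
  b <- detectDisulfides(m)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$res_i, b$res_j), c(1L, 2L))
})

test_that("matching equals the brute-force oracle on random small fixtures", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      n <- sample(3:8, 1)
      # clustered points so several candidate pairings exist
      sg <- matrix(rnorm(3 * n, sd = 1.6), ncol = 3)
      m <- cysModel(sg)
      got <- detectDisulfides(m, maxDistance = 2.5)
      want <- bruteForceMatching(sg, 2.5)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(got$res_i, unname(want[, 1]))
        expect_equal(got$res_j, unname(want[, 2]))
      }
    }
  })
})

test_that("detection respects the distance threshold and residue symmetry", {
  s <- synthStructure("groupII_ref", jitterSigma = 0.15, seed = 3)
  b <- detectDisulfides(s$model, maxDistance = 2.5)
  expect_true(all(b$sg_distance <= 2.5))
  # reversing residue order (relabelling) yields the same bond set
  m <- s$model
  n <- nResidues(m)
  rev_atoms <- m@atoms
  rev_atoms$seq_index <- n + 1L - rev_atoms$seq_index
  rev_res <- m@residues
  rev_res$seq_index <- n + 1L - rev_res$seq_index
  m2 <- new("StructureModel", id = "rev",
            residues = rev_res[order(rev_res$seq_index), ],
            atoms = rev_atoms[order(rev_atoms$seq_index), ],
            source = "synthetic")
  b2 <- detectDisulfides(m2)
  expect_setequal(paste(n + 1L - b2$res_j, n + 1L - b2$res_i),
                  paste(b$res_i, b$res_j))
})

test_that("a model without Cys gives an empty result, missing SG warns", {
  m <- synthHelixStructure(30)
  expect_equal(nrow(detectDisulfides(m)), 0L)
  # strip one SG from a bonded pair
  s <- synthStructure("groupIII_ref", seed = 2)$model
  drop <- which(s@atoms$name == "SG")[1]
  s@atoms <- s@atoms[-drop, ]
  expect_warning(detectDisulfides(s), "lack an SG")
})

test_that("bonds with low-pLDDT residues are flagged, not dropped", {
  m <- cysModel(rbind(c(0, 0, 0), c(2.05, 0, 0)), plddt = 40)
  b <- detectDisulfides(m)
  expect_equal(nrow(b), 1L)
  expect_true(b$low_confidence)
})

test_that("a reference mapped onto itself yields C1..C12, nothing lacking", {
  for (id in c("mp4g19220", "ASPR1", "APA1")) {
    ref <- referenceTopology(id)
    top <- canonicalNumbering(ref$seq, referenceBondTable(ref), ref)
    expect_equal(top@labels$label, paste0("C", 1:12))
    expect_length(top@lacking, 0)
    expect_true(all(top@labels$insertion == ""))
  }
})

test_that("an APCB1-like query against the group II reference lacks C4 with extra C6a", {
  s <- synthStructure("groupII_APCB1", seed = 4)
  b <- detectDisulfides(s$model)
  top <- canonicalNumbering(sequenceOf(s$model), b, "mp4g19220")
  expect_equal(top@lacking, "C4")
  expect_true("C6a" %in% top@labels$label)
  nap <- detectNAP1Fold(top)
  expect_setequal(nap$bonds, c("C5-C7", "C6-C6a"))
})

test_that("deleting one reference Cys and inserting another labels as expected", {
  ref <- referenceTopology("ASPR1")
  ch <- aaChars(ref$seq)
  # delete the cysteine at C5 and insert a new one 3 after C9
  c5 <- ref$cys$pos[ref$cys$base == 5]
  c9 <- ref$cys$pos[ref$cys$base == 9]
  ch[c5] <- "A"
  ch[c9 + 3L] <- "C"
  q <- paste(ch, collapse = "")
  top <- canonicalNumbering(q, NULL, ref)
  expect_true("C5" %in% top@lacking)
  expect_true("C9a" %in% top@labels$label)
  # all other base labels inherited
  expect_setequal(setdiff(paste0("C", 1:12), top@labels$label), "C5")
})

test_that("canonical numbering is idempotent on an already-canonical topology", {
  s <- synthStructure("groupIII_F", seed = 9)
  b <- detectDisulfides(s$model)
  t1 <- canonicalNumbering(sequenceOf(s$model), b, "ASPR1")
  t2 <- canonicalNumbering(sequenceOf(s$model), b, "ASPR1")
  expect_identical(topologyString(t1), topologyString(t2))
  expect_identical(t1@labels, t2@labels)
})

test_that("topology strings are canonical and order-independent", {
  s <- synthStructure("groupIII_G_var", seed = 6)
  b <- detectDisulfides(s$model)
  t1 <- canonicalNumbering(sequenceOf(s$model), b, "ASPR1")
  expect_match(topologyString(t1), "C9a-C11a")
  # permuted bond insertion order gives the same string
  t2 <- t1
  t2@bonds <- t1@bonds[rev(seq_len(nrow(t1@bonds))), ]
  expect_identical(topologyString(t1), topologyString(t2))
  # empty bond set canonical form
  t3 <- canonicalNumbering(referenceTopology("ASPR1")$seq, NULL, "ASPR1")
  expect_match(topologyString(t3), "^∅\\|lacking:-\\|extra:-$")
  expect_error(canonicalNumbering("", NULL, "ASPR1"), "empty")
})
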