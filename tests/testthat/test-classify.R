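# Structure-only feature vectors mirroring the exemplar proteins.
apa1Like <- function() featureVector("APA1like", intron_count = 10,
  has_saposin = TRUE, has_nap1 = FALSE, canonical_active_site = TRUE,
  n_bonds = 6L)
sap1Like <- function() featureVector("SAP1like", intron_count = 0,
  has_saposin = FALSE, has_nap1 = TRUE, canonical_active_site = FALSE,
  n_bonds = 6L, lacking = c("C2", "C3"), extra = c("C5a", "C5b"),
  bond_labels = c("C1-C8", "C4-C6", "C5-C7", "C5a-C5b", "C9-C12", "C10-C11"))

test_that("exemplar-style feature vectors route to their groups", {
  recI <- assignGroup(apa1Like())
  expect_equal(recI$group, "I")
  expect_true("saposin_domain" %in% recI$evidence$rule)
  recIV <- assignGroup(sap1Like())
  expect_equal(recIV$group, "IV")
  # all-unknown vector stays unassigned with empty evidence
  recU <- assignGroup(featureVector("mystery"))
  expect_equal(recU$group, "unassigned")
  expect_equal(nrow(recU$evidence), 0L)
})

test_that("unknown values never behave as FALSE in the rules", {
  # canonical_active_site unknown: the group IV rule must not fire
  fv <- featureVector("x", intron_count = 0, has_nap1 = TRUE)
  expect_equal(assignGroup(fv)$group, "III")  # fires the NAP1 rule instead
  fv2 <- featureVector("y", intron_count = 0)
  expect_equal(assignGroup(fv2)$group, "unassigned")
})

test_that("clade evidence dominates and conflicts downgrade confidence", {
  fv <- featureVector("z", clade_label = "II", intron_count = 9,
                      has_nap1 = TRUE, canonical_active_site = TRUE)
  rec <- assignGroup(fv)
  expect_equal(rec$group, "II")
  expect_equal(rec$confidence, "clade+structure")
  # conflicting structure (saposin says I, clade says III)
  fvc <- featureVector("w", clade_label = "III", has_saposin = TRUE)
  recc <- assignGroup(fvc)
  expect_equal(recc$group, "III")
  expect_equal(recc$confidence, "clade-only")
  expect_true("conflict" %in% recc$evidence$rule)
  # precedence inversion for structure-only studies
  recs <- assignGroup(fvc, cladeDominates = FALSE)
  expect_equal(recs$group, "I")
})

test_that("group I splits on the saposin-like domain", {
  a <- apa1Like()
  expect_equal(assignSubgroup(assignGroup(a), a)$subgroup, "I-A")
  b <- featureVector("IB", intron_count = 10, has_saposin = FALSE,
                     has_nap1 = FALSE, n_bonds = 3L,
                     canonical_active_site = TRUE)
  expect_equal(assignSubgroup(assignGroup(b), b)$subgroup, "I-B")
})

test_that("group II subgroups follow C-extension and GPI evidence", {
  base <- list(intron_count = 8, has_nap1 = TRUE, canonical_active_site = TRUE)
  mk <- function(id, ...) do.call(featureVector, c(list(id), base, list(...)))
  expect_equal(assignSubgroup(assignGroup(mk("a", has_c_extend = FALSE)),
                              mk("a", has_c_extend = FALSE))$subgroup, "II-A")
  fvB <- mk("b", has_c_extend = TRUE, very_long_c_extend = FALSE)
  expect_equal(assignSubgroup(assignGroup(fvB), fvB)$subgroup, "II-B")
  fvC <- mk("c", has_c_extend = TRUE, very_long_c_extend = TRUE)
  expect_equal(assignSubgroup(assignGroup(fvC), fvC)$subgroup, "II-C")
  fvD <- mk("d", has_c_extend = FALSE, annotations = "GPI")
  expect_equal(assignSubgroup(assignGroup(fvD), fvD)$subgroup, "II-D")
})

test_that("group III subgroups follow topology deltas; shared signatures stay ambiguous", {
  base <- list(intron_count = 0, has_nap1 = TRUE, canonical_active_site = TRUE)
  mk <- function(id, ...) do.call(featureVector, c(list(id), base, list(...)))
  refBonds <- c("C1-C8", "C2-C3", "C4-C6", "C5-C7", "C9-C12", "C10-C11")
  # III-A: 14 cysteines, three NAP1 bonds
  fvA <- mk("a", nap1_bonds = 3L, cys_count = 14L,
            bond_labels = c(refBonds, "C6a-C6b"))
  expect_equal(assignSubgroup(assignGroup(fvA), fvA)$subgroup, "III-A")
  # III-C/III-D: lacks C2-C3; resolvable only by the tree
  fvCD <- mk("cd", lacking = c("C2", "C3"),
             bond_labels = setdiff(refBonds, "C2-C3"))
  rcd <- assignSubgroup(assignGroup(fvCD), fvCD)
  expect_equal(rcd$subgroup, "III-C|III-D")
  expect_match(rcd$confidence, "ambiguous")
  fvD <- mk("d", clade_label = "III", clade_subgroup = "III-D",
            lacking = c("C2", "C3"), bond_labels = setdiff(refBonds, "C2-C3"))
  expect_equal(assignSubgroup(assignGroup(fvD), fvD)$subgroup, "III-D")
  # III-F: the C4-C6 bond is absent although C4 and C6 exist
  fvF <- mk("f", bond_labels = setdiff(refBonds, "C4-C6"))
  expect_equal(assignSubgroup(assignGroup(fvF), fvF)$subgroup, "III-F")
  # III-G variant: lacks C4+C5 with the extra C-terminal C9a-C11a bond
  fvG <- mk("g", lacking = c("C4", "C5"),
            bond_labels = c("C1-C8", "C2-C3", "C6-C7", "C9-C12", "C10-C11",
                            "C9a-C11a"))
  expect_equal(assignSubgroup(assignGroup(fvG), fvG)$subgroup, "III-G")
  # baseline topology: III-B vs III-G needs the tree
  fvB <- mk("b", bond_labels = refBonds, topology_string = "x")
  rb <- assignSubgroup(assignGroup(fvB), fvB)
  expect_equal(rb$subgroup, "III-B|III-G")
  expect_match(rb$confidence, "ambiguous")
  # III-E: extra interdomain helix is annotation evidence
  fvE <- mk("e", bond_labels = refBonds, annotations = "interdomain_helix")
  expect_equal(assignSubgroup(assignGroup(fvE), fvE)$subgroup, "III-E")
})

test_that("every subgroup of the scheme is reachable", {
  reached <- character()
  add <- function(rec) reached <<- c(reached, rec$subgroup)
  # group I and IV routes
  add(assignSubgroup(assignGroup(apa1Like()), apa1Like()))
  bI <- featureVector("ib", has_saposin = FALSE, n_bonds = 3L, has_nap1 = FALSE)
  add(assignSubgroup(assignGroup(bI), bI))
  add(assignSubgroup(assignGroup(sap1Like()), sap1Like()))
  # groups II & III via the batch interface
  tab <- data.frame(
    gene_id = c("iia", "iib", "iic", "iid", "iiia", "iiic", "iiid", "iiie",
                "iiif", "iiig", "iiib"),
    clade_label = c(rep("II", 4), rep("III", 7)),
    clade_subgroup = c(rep(NA, 5), "III-C", "III-D", NA, NA, NA, "III-B"),
    intron_count = c(rep(9, 4), rep(0, 7)),
    has_nap1 = TRUE, canonical_active_site = TRUE,
    has_c_extend = c(FALSE, TRUE, TRUE, FALSE, rep(FALSE, 7)),
    very_long_c_extend = c(FALSE, FALSE, TRUE, FALSE, rep(FALSE, 7)),
    annotations = c("", "", "", "GPI", "", "", "", "interdomain_helix", "", "", ""),
    nap1_bonds = c(rep(NA, 4), 3L, rep(NA, 6)),
    cys_count = c(rep(NA, 4), 14L, rep(12L, 6)),
    lacking = c(rep("", 4), "", "C2,C3", "C2,C3", "", "", "C4,C5", ""),
    bond_labels = c(rep("C1-C8,C2-C3,C4-C6,C5-C7,C9-C12,C10-C11", 5),
                    rep("C1-C8,C4-C6,C5-C7,C9-C12,C10-C11", 2),
                    "C1-C8,C2-C3,C4-C6,C5-C7,C9-C12,C10-C11",
                    "C1-C8,C2-C3,C5-C7,C9-C12,C10-C11",
                    "C1-C8,C2-C3,C6-C7,C9-C12,C10-C11,C9a-C11a",
                    "C1-C8,C2-C3,C4-C6,C5-C7,C9-C12,C10-C11"),
    stringsAsFactors = FALSE)
  out <- classifyBatch(tab)
  reached <- c(reached, out$records$subgroup)
  expect_true(all(c("I-A", "I-B", "II-A", "II-B", "II-C", "II-D",
                    "III-A", "III-C", "III-D", "III-E", "III-F", "III-G",
                    "IV") %in% reached))
  # no record carries a subgroup from another group's namespace
  expect_true(all(substr(out$records$subgroup, 1,
                         nchar(out$records$group)) == out$records$group |
                    out$records$subgroup == "none"))
})

test_that("batch classification is deterministic and rejects duplicates", {
  tab <- data.frame(gene_id = c("a", "b"), clade_label = c("I", "IV"),
                    stringsAsFactors = FALSE)
  o1 <- classifyBatch(tab); o2 <- classifyBatch(tab)
  expect_identical(o1$records, o2$records)
  expect_equal(as.integer(o1$counts[c("I", "IV")]), c(1L, 1L))
  expect_error(classifyBatch(data.frame(gene_id = c("a", "a"))), "duplicate")
  empty <- classifyBatch(data.frame(gene_id = character()))
  expect_equal(nrow(empty$records), 0L)
})
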