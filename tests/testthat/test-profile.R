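test_that("zero-pseudocount profile of identical sequences gives the closed-form score", {
  p <- buildProfile(c("ACD", "ACD"), pseudocount = 0)
  bg <- p@background
  expect_equal(p@scores[1, "A"], log2(1 / bg["A"]), ignore_attr = TRUE)
  expect_equal(p@scores[2, "C"], log2(1 / bg["C"]), ignore_attr = TRUE)
  expect_equal(p@consensus, "ACD")
})

test_that("column scores equal hand-computed log-odds with pseudocount 0.1", {
  aln <- c("AC", "AC", "AD")
  p <- buildProfile(aln, pseudocount = 0.1)
  q <- p@background
  # column 1: 3 A of 3 -> p_A = (3 + 0.1 q_A) / 3.1
  expect_equal(p@scores[1, "A"],
               log2(((3 + 0.1 * q["A"]) / 3.1) / q["A"]), ignore_attr = TRUE)
  # column 2: 2 C, 1 D
  expect_equal(p@scores[2, "C"],
               log2(((2 + 0.1 * q["C"]) / 3.1) / q["C"]), ignore_attr = TRUE)
  expect_equal(p@scores[2, "D"],
               log2(((1 + 0.1 * q["D"]) / 3.1) / q["D"]), ignore_attr = TRUE)
  # probabilities renormalise to 1
  probs <- (c(2, 1) + 0.1 * q[c("C", "D")]) / 3.1
  rest <- 0.1 * q[setdiff(names(q), c("C", "D"))] / 3.1
  expect_equal(sum(probs) + sum(rest), 1, tolerance = 1e-9)
})

test_that("mostly-gapped columns are dropped and empty alignments error", {
  p <- buildProfile(c("A-C", "A-C", "ADC"), pseudocount = 0.1)
  expect_equal(nrow(p@scores), 2L)   # middle column is 2/3 gaps
  expect_error(buildProfile(character(0)), "at least 2")
})

test_that("the consensus sequence is always a hit and scores the self-score", {
  fam <- synthFamily(12, seed = 3)
  p <- buildProfile(substr(fam$alignment, 80, 200))
  hits <- searchProfile(p, setNames(p@consensus, "consensus"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$best_score, profileSelfScore(p), tolerance = 1e-9)
})

test_that("consensus outscores every single-point mutant when columns have unique maxima", {
  p <- buildProfile(c("ACDEF", "ACDEF", "ACDEF"), pseudocount = 0.1)
  cons <- aaChars(p@consensus)
  base <- profileSelfScore(p)
  for (i in seq_along(cons)) {
    mut <- cons
    mut[i] <- setdiff(c("W", "Y"), cons[i])[1]
    sc <- searchProfile(p, paste(mut, collapse = ""), threshold = -1e9)$best_score
    expect_lt(sc, base)
  }
})

test_that("a planted-motif family is fully recovered with correct offsets", {
  withr::with_seed(31, {
    L <- 40L
    motif <- paste(sample(AA_ALPHABET_TEST, L, replace = TRUE), collapse = "")
    seqs <- character(20); offs <- integer(20)
    for (i in 1:20) {
      pre <- sample(60:120, 1)
      offs[i] <- pre + 1L
      seqs[i] <- paste0(
        paste(sample(AA_ALPHABET_TEST, pre, TRUE), collapse = ""), motif,
        paste(sample(AA_ALPHABET_TEST, 50, TRUE), collapse = ""))
    }
    names(seqs) <- paste0("fam", 1:20)
    prof <- buildProfile(rep(motif, 3), pseudocount = 0.1)
    hits <- searchProfile(prof, seqs)
    expect_setequal(hits$seq_id, names(seqs))
    expect_equal(hits$start[match(names(seqs), hits$seq_id)], offs)
  })
})

test_that("shuffled decoys produce no hits at the default threshold", {
  fam <- synthFamily(12, seed = 7)
  prof <- buildProfile(substr(fam$alignment, 80, 200))
  withr::with_seed(42, {
    decoys <- vapply(1:1000, function(i)
      paste(sample(AA_ALPHABET_TEST, 180, TRUE), collapse = ""), character(1))
  })
  hits <- searchProfile(prof, decoys)
  expect_lte(nrow(hits) / 1000, 0.01)
})

test_that("one round equals plain search and a full-family seed is a fixed point", {
  fam <- synthFamily(16, seed = 9)
  window <- substr(fam$alignment, 80, 200)
  prof <- buildProfile(window)
  one <- iterativeSearch(prof, fam$alignment, rounds = 1)
  plain <- searchProfile(prof, fam$alignment)
  expect_equal(one$hits[[1]], plain)
  two <- iterativeSearch(prof, fam$alignment, rounds = 2)
  expect_length(two$gained[[1]], 0)
})

test_that("round 2 recovers a divergent subfamily missed by the seed profile", {
  withr::with_seed(33, {
    L <- 100L
    s0 <- sample(AA_ALPHABET_TEST, L, replace = TRUE)
    mutate <- function(s, at) {
      s[at] <- vapply(s[at], function(a) sample(setdiff(AA_ALPHABET_TEST, a), 1),
                      character(1))
      s
    }
    # at the default threshold (60% of self-score, ~4.4 bits/match vs ~-5
    # bits/mismatch) a hit needs roughly >= 81% identity: the bridge member
    # (88%) passes round 1, the divergent member (72%) only passes once the
    # rebuilt profile has absorbed the bridge's subfamily-defining columns
    bridgeSites <- sample(L, 12)
    farSites <- sample(setdiff(seq_len(L), bridgeSites), 16)
    bridge <- mutate(s0, bridgeSites)
    divergent <- mutate(bridge, farSites)
    db <- c(seed1 = paste(s0, collapse = ""),
            seed2 = paste(mutate(s0, sample(L, 4)), collapse = ""),
            bridge = paste(bridge, collapse = ""),
            far = paste(divergent, collapse = ""))
    prof <- buildProfile(rep(db[["seed1"]], 3), pseudocount = 0.1)
    res <- iterativeSearch(prof, db, rounds = 2)
    expect_false("far" %in% res$hits[[1]]$seq_id)  # missed by the seed
    expect_true("far" %in% res$hits[[2]]$seq_id)   # recovered after rebuild
    expect_true("far" %in% res$gained[[1]])
  })
})
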