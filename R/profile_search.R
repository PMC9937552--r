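## Iterative position-specific scoring search. The family-identification
## procedure is two-round: a seed profile finds a first hit set, the profile
## is rebuilt from the hit regions, and the rebuilt profile is searched
## again, which recovers divergent members the seed misses. The profile is a
## PSSM (per-column log-odds in bits against a background composition), not
## a full profile HMM: the two-round logic is the point, not Plan7.

#' Build a position-specific scoring matrix from an alignment
#'
#' Columns with more than 50% gaps are dropped. Per column, residue
#' probabilities are estimated with Dirichlet-style pseudocounts against the
#' background: p_a = (n_a + w q_a) / (N + w), where w is
#' \code{pseudocount} and q the background frequency; scores are
#' log2(p_a / q_a) bits.
#'
#' @param alignment Named character vector or AAStringSet of equal-width
#'   aligned sequences (gap "-").
#' @param pseudocount Total pseudocount weight w (default 0.1).
#' @param background Length-20 background frequencies (default
#'   Robinson-Robinson).
#' @param maxGapFraction Columns with a higher gap fraction are dropped
#'   (default 0.5).
#' @return A \linkS4class{Profile}.
#' @examples
#' p <- buildProfile(c(a = "ACDE", b = "ACDE"), pseudocount = 0)
#' p@consensus
#' @export
buildProfile <- function(alignment, pseudocount = 0.1,
                         background = ROBINSON_BACKGROUND,
                         maxGapFraction = 0.5) {
  aln <- as.character(alignment)
  if (length(aln) < 2L) stop("need at least 2 aligned sequences", call. = FALSE)
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must have equal width", call. = FALSE)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  gapFrac <- colMeans(m == "-" | m == ".")
  keep <- which(gapFrac <= maxGapFraction)
  if (length(keep) == 0L) stop("all columns exceed the gap threshold", call. = FALSE)
  m <- m[, keep, drop = FALSE]
  L <- ncol(m)
  q <- background[AA_ALPHABET]
  scores <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col %in% AA_ALPHABET]
    n <- table(factor(col, levels = AA_ALPHABET))
    p <- (as.numeric(n) + pseudocount * q) / (length(col) + pseudocount)
    ## zero-pseudocount columns can contain -Inf log-odds; clamp to a floor
    ## so scores stay finite (an absent residue is strongly penalised)
    s <- log2(p / q)
    s[!is.finite(s)] <- -20
    scores[j, ] <- s
  }
  new("Profile",
      scores = scores,
      consensus = paste(AA_ALPHABET[max.col(scores, ties.method = "first")],
                        collapse = ""),
      background = q,
      pseudocount = pseudocount)
}

## Per-sequence best ungapped window score of a profile.
bestWindow <- function(profile, seqstr) {
  S <- profile@scores
  L <- nrow(S)
  x <- match(aaChars(seqstr), AA_ALPHABET)
  n <- length(x)
  if (n < L) return(c(score = -Inf, start = NA_real_))
  ## unknown residues score 0 in every column
  M <- cbind(S, X = 0)
  x[is.na(x)] <- 21L
  best <- -Inf; bestAt <- NA_integer_
  rows <- seq_len(L)
  for (off in 0:(n - L)) {
    sc <- sum(M[cbind(rows, x[rows + off])])
    if (sc > best) { best <- sc; bestAt <- off + 1L }
  }
  c(score = best, start = bestAt)
}

#' Maximum self-score of a profile
#'
#' Sum of the per-column maxima; the score its own consensus achieves.
#' @param profile A \linkS4class{Profile}.
#' @return Numeric (bits).
#' @export
profileSelfScore <- function(profile) sum(apply(profile@scores, 1, max))

#' Search sequences with a profile
#'
#' Slides the profile over each sequence (ungapped) and keeps the best
#' window. Sequences scoring at least \code{threshold} are hits, sorted by
#' descending score.
#'
#' @param profile A \linkS4class{Profile}.
#' @param sequences Named character vector (or AAStringSet) of protein
#'   sequences.
#' @param threshold Bit-score threshold; default 60% of the profile
#'   self-score (no E-value machinery here).
#' @return data.frame(seq_id, best_score, start, end) of hits.
#' @export
searchProfile <- function(profile, sequences, threshold = NULL) {
  seqs <- asNamedChar(sequences)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(threshold)) threshold <- 0.6 * profileSelfScore(profile)
  stopifnot(is.finite(threshold))
  L <- nrow(profile@scores)
  bw <- vapply(seqs, bestWindow, numeric(2), profile = profile)
  out <- data.frame(seq_id = names(seqs),
                    best_score = bw["score", ],
                    start = as.integer(bw["start", ]),
                    end = as.integer(bw["start", ]) + L - 1L,
                    stringsAsFactors = FALSE)
  out <- out[is.finite(out$best_score) & out$best_score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out[order(-out$best_score), , drop = FALSE]
}

#' Two-round iterative profile search
#'
#' Round 1 searches with the seed profile. For each later round the profile
#' is rebuilt from the hit windows of the previous round (windows are
#' profile-anchored and ungapped, hence mutually aligned) and the search is
#' repeated. Later rounds are not guaranteed to be supersets of earlier
#' ones; gained and lost identifiers are reported per round.
#'
#' @param seedProfile A \linkS4class{Profile} (or an alignment from which one
#'   is built).
#' @param sequences Named character vector of protein sequences.
#' @param threshold Bit threshold; default 60% of each round's profile
#'   self-score.
#' @param rounds Number of rounds (>= 1; default 2).
#' @param pseudocount Pseudocount for rebuilt profiles.
#' @return list(hits = list of per-round hit frames, gained, lost,
#'   profiles). Stops early (with a message) on a round with zero hits.
#' @export
iterativeSearch <- function(seedProfile, sequences, threshold = NULL,
                            rounds = 2L, pseudocount = 0.1) {
  stopifnot(rounds >= 1L)
  if (!is(seedProfile, "Profile")) seedProfile <- buildProfile(seedProfile,
                                                               pseudocount)
  seqs <- asNamedChar(sequences)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  profiles <- list(seedProfile)
  hits <- list()
  gained <- list(); lost <- list()
  for (r in seq_len(rounds)) {
    prof <- profiles[[r]]
    hits[[r]] <- searchProfile(prof, seqs, threshold)
    if (nrow(hits[[r]]) == 0L) {
      message("round ", r, " produced no hits; stopping early")
      break
    }
    if (r > 1L) {
      gained[[r - 1L]] <- setdiff(hits[[r]]$seq_id, hits[[r - 1L]]$seq_id)
      lost[[r - 1L]] <- setdiff(hits[[r - 1L]]$seq_id, hits[[r]]$seq_id)
    }
    if (r < rounds) {
      h <- hits[[r]]
      windows <- substr(seqs[h$seq_id], h$start, h$end)
      profiles[[r + 1L]] <- if (length(windows) >= 2L)
        buildProfile(windows, pseudocount, maxGapFraction = 1) else prof
    }
  }
  list(hits = hits, gained = gained, lost = lost, profiles = profiles)
}
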