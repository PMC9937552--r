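#' StructureModel: a single-chain protein structure with confidence values
#'
#' Uniform container for one protein chain parsed from a PDB file (predicted
#' AlphaFold-style models carry per-residue pLDDT in the B-factor column) or
#' built by the synthetic generator. Residues are stored as a data frame
#' (\code{seq_index}, \code{aa}, \code{plddt}) and atoms as a data frame
#' (\code{seq_index}, \code{name}, \code{element}, \code{x}, \code{y},
#' \code{z}).
#'
#' @slot id Model identifier.
#' @slot residues data.frame with columns seq_index, aa, plddt.
#' @slot atoms data.frame with columns seq_index, name, element, x, y, z.
#' @slot source Either "predicted" or "experimental".
#' @exportClass StructureModel
setClass("StructureModel",
  representation(
    id = "character",
    residues = "data.frame",
    atoms = "data.frame",
    source = "character"
  )
)

setValidity("StructureModel", function(object) {
  r <- object@residues
  a <- object@atoms
  msg <- character()
  if (nrow(r) == 0L) msg <- c(msg, "model has no residues")
  if (!all(c("seq_index", "aa", "plddt") %in% names(r)))
    msg <- c(msg, "residues must have seq_index, aa, plddt")
  if (nrow(r) > 1L && any(diff(r$seq_index) <= 0L))
    msg <- c(msg, "residue seq_index must be strictly increasing")
  if (any(r$plddt < 0 | r$plddt > 100, na.rm = TRUE))
    msg <- c(msg, "pLDDT values must lie in [0, 100]")
  if (!all(c("seq_index", "name", "x", "y", "z") %in% names(a)))
    msg <- c(msg, "atoms must have seq_index, name, x, y, z")
  if (nrow(a) > 0L) {
    if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
      msg <- c(msg, "atom coordinates must be finite")
    if (anyDuplicated(paste(a$seq_index, a$name)))
      msg <- c(msg, "at most one atom per (residue, atom-name)")
  }
  if (!object@source %in% c("predicted", "experimental", "synthetic"))
    msg <- c(msg, "source must be predicted, experimental or synthetic")
  if (length(msg)) msg else TRUE
})

#' DisulfideTopology: labelled disulfide bonds of one model
#'
#' The detected S-S bonds of a model expressed in a canonical reference
#' cysteine numbering (C1..CN, insertion-coded extras such as C6a), together
#' with reference labels absent from the query ("lacking").
#'
#' @slot model_id Query model identifier.
#' @slot reference_id Identifier of the reference numbering used.
#' @slot labels data.frame: seq_index, label, base, insertion for every query Cys.
#' @slot bonds data.frame: res_i, res_j, label_i, label_j, sg_distance, flagged.
#' @slot lacking Character vector of reference labels with no query counterpart.
#' @exportClass DisulfideTopology
setClass("DisulfideTopology",
  representation(
    model_id = "character",
    reference_id = "character",
    labels = "data.frame",
    bonds = "data.frame",
    lacking = "character"
  )
)

setValidity("DisulfideTopology", function(object) {
  msg <- character()
  lb <- object@labels
  if (nrow(lb) > 1L && any(diff(lb$seq_index) <= 0L))
    msg <- c(msg, "labelled cysteines must be strictly increasing in seq_index")
  b <- object@bonds
  if (nrow(b) > 0L) {
    cys <- c(b$res_i, b$res_j)
    if (anyDuplicated(cys)) msg <- c(msg, "each cysteine may appear in at most one bond")
    if (any(b$res_i >= b$res_j)) msg <- c(msg, "bonds must have res_i < res_j")
  }
  if (length(msg)) msg else TRUE
})

#' SuperpositionResult: rigid-body superposition outcome
#'
#' @slot rotation 3x3 proper rotation matrix applied to the mobile model.
#' @slot translation Length-3 translation vector (Angstrom).
#' @slot rmsd RMSD (Angstrom) over the retained pairs.
#' @slot rmsd_initial RMSD of the first cycle before any rejection.
#' @slot n_start,n_retained Pair counts before/after outlier rejection.
#' @slot cycles_run Number of fit cycles executed.
#' @slot flags Character vector of diagnostics (e.g. "degenerate", "low_coverage").
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(
    rotation = "matrix",
    translation = "numeric",
    rmsd = "numeric",
    rmsd_initial = "numeric",
    n_start = "integer",
    n_retained = "integer",
    cycles_run = "integer",
    flags = "character"
  )
)

setValidity("SuperpositionResult", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation must be orthonormal within 1e-8")
    if (abs(det(R) - 1) > 1e-6) msg <- c(msg, "rotation must be proper (det = +1)")
  }
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (object@n_retained > object@n_start)
    msg <- c(msg, "n_retained cannot exceed n_start")
  if (length(msg)) msg else TRUE
})

#' Profile: position-specific scoring matrix in bits
#'
#' @slot scores L x 20 matrix of log-odds scores (bits), columns named by the
#'   one-letter alphabet.
#' @slot consensus Consensus string (per-column argmax).
#' @slot background Length-20 background frequency vector.
#' @slot pseudocount Total Dirichlet pseudocount weight used.
#' @exportClass Profile
setClass("Profile",
  representation(
    scores = "matrix",
    consensus = "character",
    background = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("Profile", function(object) {
  msg <- character()
  if (ncol(object@scores) != 20L) msg <- c(msg, "profile must have 20 columns")
  if (nrow(object@scores) < 1L) msg <- c(msg, "profile must have at least one column (L >= 1)")
  if (!all(is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

#' TrimmedAlignment: entropy-trimmed multiple sequence alignment
#'
#' @slot kept_columns Indices (into the input MSA) of retained columns.
#' @slot sequences Named character vector of trimmed aligned sequences.
#' @slot entropy Normalised per-input-column Shannon entropy in [0, 1].
#' @slot gap_fraction Per-input-column gap fraction.
#' @exportClass TrimmedAlignment
setClass("TrimmedAlignment",
  representation(
    kept_columns = "integer",
    sequences = "character",
    entropy = "numeric",
    gap_fraction = "numeric"
  )
)

setValidity("TrimmedAlignment", function(object) {
  msg <- character()
  if (length(object@kept_columns) > 1L && any(diff(object@kept_columns) <= 0L))
    msg <- c(msg, "kept_columns must be strictly increasing")
  w <- unique(nchar(object@sequences))
  if (length(w) > 1L) msg <- c(msg, "trimmed sequences must have equal length")
  if (any(object@entropy < -1e-12 | object@entropy > 1 + 1e-12))
    msg <- c(msg, "normalised entropy must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
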