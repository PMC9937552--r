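#' Amino-acid sequence of a structure model
#'
#' @param model A \linkS4class{StructureModel}.
#' @return One-letter amino-acid string of length \code{nResidues(model)};
#'   residues outside the standard 20 appear as \code{"X"}.
#' @export
setGeneric("sequenceOf", function(model) standardGeneric("sequenceOf"))

#' Canonical serialization of a disulfide topology
#'
#' @param topology A \linkS4class{DisulfideTopology}.
#' @return Deterministic string such as
#'   \code{"C1-C8;C2-C3;C5-C7|lacking:C4|extra:C6a"}; identical topologies
#'   yield identical strings regardless of bond insertion order.
#' @export
setGeneric("topologyString", function(topology) standardGeneric("topologyString"))

#' @describeIn StructureModel Number of residues.
#' @param model A StructureModel.
#' @export
nResidues <- function(model) nrow(model@residues)

#' @describeIn StructureModel Model identifier.
#' @export
modelId <- function(model) model@id

#' @describeIn StructureModel Residue table (seq_index, aa, plddt).
#' @param x A StructureModel.
#' @export
modelResidues <- function(x) x@residues

#' Coordinates of one named atom per residue
#'
#' @param model A \linkS4class{StructureModel}.
#' @param atom Atom name, e.g. \code{"CA"} or \code{"SG"}.
#' @return Numeric matrix (n x 3) with rownames = residue \code{seq_index};
#'   only residues that carry the atom are included.
#' @export
atomCoords <- function(model, atom = "CA") {
  a <- model@atoms[model@atoms$name == atom, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$seq_index
  m
}

#' Extract a contiguous residue slice of a model
#'
#' @param model A \linkS4class{StructureModel}.
#' @param from,to 1-based positions within the residue list (inclusive).
#' @return A new StructureModel covering residues \code{from..to}.
#' @export
sliceModel <- function(model, from, to) {
  stopifnot(from >= 1L, to <= nResidues(model), from <= to)
  keep <- model@residues$seq_index[from:to]
  new("StructureModel",
      id = paste0(model@id, "[", from, "-", to, "]"),
      residues = model@residues[model@residues$seq_index %in% keep, , drop = FALSE],
      atoms = model@atoms[model@atoms$seq_index %in% keep, , drop = FALSE],
      source = model@source)
}

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel '", object@id, "' (", object@source, ")\n", sep = "")
  cat("  residues: ", nResidues(object),
      "; atoms: ", nrow(object@atoms),
      "; mean pLDDT: ", round(mean(object@residues$plddt), 1), "\n", sep = "")
})

setMethod("show", "DisulfideTopology", function(object) {
  cat("DisulfideTopology for '", object@model_id,
      "' in reference '", object@reference_id, "'\n", sep = "")
  cat("  ", topologyString(object), "\n", sep = "")
})

setMethod("show", "SuperpositionResult", function(object) {
  cat("SuperpositionResult: RMSD = ", format(object@rmsd, digits = 4),
      " A over ", object@n_retained, "/", object@n_start,
      " pairs (", object@cycles_run, " cycle",
      if (object@cycles_run != 1L) "s", ")\n", sep = "")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "Profile", function(object) {
  cat("Profile of length ", nrow(object@scores),
      " (pseudocount ", object@pseudocount, ")\n", sep = "")
  cat("  consensus: ", object@consensus, "\n", sep = "")
})

setMethod("show", "TrimmedAlignment", function(object) {
  cat("TrimmedAlignment: ", length(object@sequences), " sequences, ",
      length(object@kept_columns), "/", length(object@entropy),
      " columns kept\n", sep = "")
})

#' @describeIn SuperpositionResult Final RMSD (Angstrom) over retained pairs.
#' @param x A SuperpositionResult.
#' @export
superRmsd <- function(x) x@rmsd

#' @describeIn DisulfideTopology Bond table (res_i, res_j, labels, distance).
#' @param x A DisulfideTopology.
#' @export
topologyBonds <- function(x) x@bonds

#' @describeIn DisulfideTopology Reference labels missing from the query.
#' @export
topologyLacking <- function(x) x@lacking

#' @describeIn TrimmedAlignment Retained column indices.
#' @param x A TrimmedAlignment.
#' @export
keptColumns <- function(x) x@kept_columns
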