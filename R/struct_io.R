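#' Read a single-chain structure model from a PDB file
#'
#' Parses ATOM records (HETATM is ignored) of one chain into a
#' \linkS4class{StructureModel}. For predicted models the per-residue pLDDT
#' confidence is taken from the B-factor column (AlphaFold convention).
#' Insertion-coded residues are renumbered sequentially, so residue indices in
#' the returned model are 1..n along the chain. Alternate locations are
#' resolved per atom name by keeping the highest-occupancy record (ties: first
#' record wins).
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier, or \code{"first"} (default) for the first
#'   chain occurring in the file. AlphaFold plant models are monomeric, so the
#'   default is almost always what is wanted.
#' @param source \code{"predicted"} (default; B-factor read as pLDDT) or
#'   \code{"experimental"} (B-factor ignored, pLDDT set to 100).
#' @return A \linkS4class{StructureModel}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' m0 <- synthStructure(synthTopologyTemplate("groupIII_ref"), seed = 1)$model
#' writeStructure(m0, pdb)
#' m <- readStructure(pdb, source = "synthetic")
#' nResidues(m)
#' @export
readStructure <- function(path, chain = "first",
                          source = c("predicted", "experimental", "synthetic")) {
  source <- match.arg(source)
  if (!file.exists(path))
    stop("PDB file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0L)
    stop("no ATOM records in '", path, "'", call. = FALSE)

  atom$chain[is.na(atom$chain)] <- " "
  if (identical(chain, "first")) {
    chain <- atom$chain[1L]
  } else if (!chain %in% atom$chain) {
    stop("chain '", chain, "' not present in '", path, "' (chains: ",
         paste(unique(atom$chain), collapse = ", "), ")", call. = FALSE)
  }
  atom <- atom[atom$chain == chain, , drop = FALSE]

  ## Resolve altlocs: within each (resno, insert, atom-name), keep the record
  ## with highest occupancy; ties and missing occupancies keep the first.
  atom$insert[is.na(atom$insert)] <- ""
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$resno, atom$insert, atom$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -occ, seq_len(nrow(atom)))
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(paste(atom$resno, atom$insert, atom$elety, sep = "\r")), ,
               drop = FALSE]

  ## Sequential renumbering in file order of (resno, insert) groups; this
  ## absorbs insertion codes and numbering gaps.
  rkey <- paste(atom$resno, atom$insert, sep = "\r")
  seq_index <- as.integer(factor(rkey, levels = unique(rkey)))
  atom <- atom[order(seq_index, seq_len(nrow(atom))), , drop = FALSE]
  seq_index <- sort(seq_index)

  first <- !duplicated(seq_index)
  plddt <- vapply(split(atom$b, seq_index), function(b) {
    b <- b[!is.na(b)]
    if (length(b)) mean(b) else NA_real_
  }, numeric(1))
  if (source != "predicted") plddt[] <- 100
  plddt[is.na(plddt)] <- if (source == "predicted") 0 else 100
  plddt <- pmin(pmax(plddt, 0), 100)

  residues <- data.frame(
    seq_index = unique(seq_index),
    aa = aaThreeToOne(atom$resid[first]),
    plddt = unname(plddt),
    stringsAsFactors = FALSE
  )
  elem <- atom$elesy
  elem[is.na(elem) | elem == ""] <- substr(gsub("[0-9]", "", atom$elety), 1, 1)[
    is.na(elem) | elem == ""]
  atoms <- data.frame(
    seq_index = seq_index,
    name = atom$elety,
    element = elem,
    x = atom$x, y = atom$y, z = atom$z,
    stringsAsFactors = FALSE
  )
  new("StructureModel",
      id = sub("\\.pdb$", "", basename(path)),
      residues = residues, atoms = atoms, source = source)
}

#' Write a StructureModel to a PDB file
#'
#' Residue pLDDT is written to the B-factor column, so AlphaFold-style files
#' round-trip through \code{\link{readStructure}}.
#'
#' @param model A \linkS4class{StructureModel}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(model, path) {
  a <- model@atoms
  r <- model@residues
  aa1to3 <- setNames(names(AA_THREE2ONE), unname(AA_THREE2ONE))
  resid3 <- aa1to3[r$aa[match(a$seq_index, r$seq_index)]]
  resid3[is.na(resid3)] <- "UNK"
  b <- r$plddt[match(a$seq_index, r$seq_index)]
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$seq_index,
    resid = unname(resid3),
    eleno = seq_len(nrow(a)),
    elety = a$name,
    chain = rep("A", nrow(a)),
    o = rep(1, nrow(a)),
    b = b,
    elesy = a$element
  )
  invisible(path)
}

#' @rdname sequenceOf
#' @export
setMethod("sequenceOf", "StructureModel", function(model) {
  paste(model@residues$aa, collapse = "")
})

#' Summarise structure models as a table
#'
#' @param models A list of \linkS4class{StructureModel} objects.
#' @param path Optional path; when given, the table is written as TSV.
#' @return data.frame with columns id, n_residues, mean_plddt.
#' @export
structureSummary <- function(models, path = NULL) {
  if (is(models, "StructureModel")) models <- list(models)
  out <- data.frame(
    id = vapply(models, modelId, character(1)),
    n_residues = vapply(models, nResidues, integer(1)),
    mean_plddt = vapply(models, function(m) mean(m@residues$plddt), numeric(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
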