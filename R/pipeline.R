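## End-to-end orchestration: identify inputs -> tree -> per-gene features ->
## classification, with per-stage logging, per-gene degradation (one broken
## structure never aborts the batch) and reproducible outputs (the config
## hash and seed are recorded in the report).

## FNV-1a 32-bit hash of a string; used to stamp outputs with a config hash.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    h <- (h %% 2^32) * 16777619 %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Extract classification features from one gene's data
#'
#' Runs the structural stages (disulfide detection, canonical numbering
#' against the group-conventional reference, saposin/NAP1/C-extension/TM
#' annotation, active-site scan) and assembles the flat feature row that
#' \code{\link{classifyBatch}} consumes.
#'
#' @param gene_id Gene identifier.
#' @param model A \linkS4class{StructureModel}, or NULL (structure stage
#'   degraded: structural features stay unknown).
#' @param seq Protein sequence; defaults to the model's sequence.
#' @param intron_count Intron count (NA if no gene model).
#' @param clade_label,clade_subgroup Tree-derived labels (NA without a tree).
#' @param annotations Character vector of external annotations.
#' @return A one-row data.frame feature row.
#' @export
extractFeatures <- function(gene_id, model = NULL, seq = NULL,
                            intron_count = NA_real_,
                            clade_label = NA_character_,
                            clade_subgroup = NA_character_,
                            annotations = character()) {
  row <- data.frame(gene_id = gene_id, intron_count = intron_count,
                    clade_label = clade_label, clade_subgroup = clade_subgroup,
                    has_saposin = NA, has_nap1 = NA, has_c_extend = NA,
                    very_long_c_extend = NA, has_tm_helix = NA,
                    canonical_active_site = NA,
                    n_bonds = NA_integer_, nap1_bonds = NA_integer_,
                    cys_count = NA_integer_, interdomain_strands = NA_integer_,
                    topology_string = NA_character_, lacking = NA_character_,
                    extra = NA_character_, bond_labels = NA_character_,
                    annotations = paste(annotations, collapse = ","),
                    degraded = is.null(model) && is.null(seq),
                    stringsAsFactors = FALSE)
  if (is.null(model) && is.null(seq)) return(row)
  if (is.null(seq)) seq <- sequenceOf(model)
  row$cys_count <- sum(aaChars(seq) == "C")

  bonds <- NULL
  sap <- NULL
  if (!is.null(model)) {
    bonds <- detectDisulfides(model)
    row$n_bonds <- nrow(bonds)
    sap <- detectSaposinLike(model, bonds)
    row$has_saposin <- !is.null(sap)
  }
  ref <- if (!is.na(clade_label)) referenceForGroup(clade_label)
         else if (isTRUE(row$has_saposin)) referenceTopology("APA1")
         else referenceTopology("ASPR1")
  act <- scanActiveSites(seq, reference = ref)
  row$canonical_active_site <- act$canonical
  tm <- detectTMHelix(seq)
  prosegEnd <- if (!is.na(act$pos1)) act$pos1 else nchar(seq)
  row$has_tm_helix <- any(tm$start < prosegEnd)

  if (!is.null(model)) {
    top <- canonicalNumbering(seq, bonds, ref, modelId = gene_id)
    nap <- detectNAP1Fold(top)
    row$has_nap1 <- !is.null(nap)
    row$nap1_bonds <- if (is.null(nap)) 0L else nap$n_bonds
    lb <- top@labels
    coreCys <- lb$seq_index[lb$base >= 1L & lb$base <= 12L & lb$insertion == ""]
    if (length(coreCys)) {
      cext <- detectCExtend(model, max(coreCys))
      row$has_c_extend <- !is.null(cext)
      row$very_long_c_extend <- if (is.null(cext)) FALSE else cext$very_long
    }
    b <- top@bonds
    if (nrow(b)) {
      ki <- labelKey(lb$base[match(b$label_i, lb$label)],
                     lb$insertion[match(b$label_i, lb$label)])
      kj <- labelKey(lb$base[match(b$label_j, lb$label)],
                     lb$insertion[match(b$label_j, lb$label)])
      l1 <- ifelse(ki <= kj, b$label_i, b$label_j)
      l2 <- ifelse(ki <= kj, b$label_j, b$label_i)
      row$bond_labels <- paste(paste0(l1, "-", l2)[order(pmin(ki, kj))],
                               collapse = ",")
    } else row$bond_labels <- ""
    row$topology_string <- topologyString(top)
    row$lacking <- paste(top@lacking, collapse = ",")
    row$extra <- paste(lb$label[lb$insertion != ""], collapse = ",")
  }
  row
}

#' Run the full classification pipeline
#'
#' Stages, in dependency order: input acquisition (either the synthetic
#' bundle or user-supplied MSA/GFF3/PDB-directory/tree paths), alignment
#' trimming + NJ tree + anchor clade labels, intron counting, per-gene
#' structural feature extraction, rule-based classification, and report
#' writing. Failure of one gene's structure stage marks that gene degraded
#' (clade/gene-structure evidence only) and never aborts the batch.
#'
#' @param config A list, or path to a YAML file, with (all optional):
#'   \describe{
#'     \item{synth}{list(n_genes, seed, jitter_sigma) — generate the
#'       synthetic study bundle.}
#'     \item{inputs}{list(msa, gff, pdb_dir, tree, anchors) — file paths;
#'       anchors is a TSV (leaf, group).}
#'     \item{params}{list(trim_cutoff = 0.8, max_gap = 0.5,
#'       bootstrap = 0, distance = "p")}
#'     \item{outdir}{Output directory (default: tempdir subdir).}
#'     \item{seed}{Seed recorded and used for any stage randomness.}
#'   }
#' @return list(records, counts, intron_stats, features, tree, clades,
#'   degraded, outdir, config_hash, status) — status 0 = success, 3 = some
#'   genes degraded.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$synth) && is.null(config$inputs))
    stop("config must provide either 'synth' or 'inputs'", call. = FALSE)
  params <- modifyList(list(trim_cutoff = 0.8, max_gap = 0.5, bootstrap = 0L,
                            distance = "p"), config$params %||% list())
  seed <- as.integer(config$seed %||% config$synth$seed %||% 1L)
  outdir <- config$outdir %||% file.path(tempdir(), paste0("apclass_run_", seed))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfgHash <- fnv1a(jsonlite::toJSON(config[setdiff(names(config), "outdir")],
                                    auto_unbox = TRUE))
  log <- function(...) message("[apclass] ", ...)

  ## ---- stage: inputs -------------------------------------------------
  bundle <- NULL
  if (!is.null(config$synth)) {
    log("generating synthetic bundle (n=", config$synth$n_genes %||% 200L,
        ", seed=", seed, ")")
    bundle <- synthBundle(nGenes = as.integer(config$synth$n_genes %||% 200L),
                          seed = seed,
                          jitterSigma = config$synth$jitter_sigma %||% 0.2)
    aln <- bundle$family$alignment
    gffPath <- file.path(outdir, "genes.gff3")
    writeLines(bundle$gff$text, gffPath)
    anchors <- bundle$family$anchors
    treePath <- NULL
  } else {
    inp <- config$inputs
    aln <- if (!is.null(inp$msa)) readFastaSeqs(inp$msa) else NULL
    gffPath <- inp$gff
    treePath <- inp$tree
    anchors <- if (!is.null(inp$anchors)) {
      at <- utils::read.delim(inp$anchors, header = TRUE,
                              stringsAsFactors = FALSE)
      setNames(at[[2]], at[[1]])
    } else NULL
  }

  ## ---- stage: tree / clades ------------------------------------------
  clades <- NULL; tree <- NULL
  if (!is.null(treePath)) {
    tree <- ape::read.tree(treePath)
  } else if (!is.null(aln) && length(aln) >= 4L) {
    log("trimming alignment (entropy cutoff ", params$trim_cutoff, ") and building NJ tree")
    trimmed <- entropyTrim(aln, params$trim_cutoff, params$max_gap)
    tree <- if (params$bootstrap > 0L)
      bootstrapSupports(trimmed, params$bootstrap, seed = seed,
                        model = params$distance)
    else njTree(distanceMatrix(trimmed, params$distance))
  }
  if (!is.null(tree) && !is.null(anchors)) clades <- cladeAssign(tree, anchors)

  ## ---- stage: introns -------------------------------------------------
  intronCounts <- NULL
  if (!is.null(gffPath) && file.exists(gffPath)) {
    log("counting introns from ", gffPath)
    intronCounts <- countIntrons(readGeneModels(gffPath))
  }

  ## ---- stage: per-gene features ---------------------------------------
  geneIds <- unique(c(names(aln), names(intronCounts), names(clades)))
  degraded <- character()
  rows <- vector("list", length(geneIds))
  for (k in seq_along(geneIds)) {
    id <- geneIds[k]
    model <- NULL
    seq <- if (!is.null(aln) && id %in% names(aln))
      gsub("-", "", aln[[id]], fixed = TRUE) else NULL
    rows[[k]] <- tryCatch({
      if (!is.null(bundle) && id %in% names(bundle$templates)) {
        model <- synthStructure(bundle$templates[[id]],
                                jitterSigma = bundle$jitterSigma,
                                seed = childSeed(seed, k))$model
        seq <- sequenceOf(model)
      } else if (!is.null(config$inputs$pdb_dir)) {
        pdb <- file.path(config$inputs$pdb_dir, paste0(id, ".pdb"))
        if (file.exists(pdb)) model <- readStructure(pdb)
      }
      annot <- if (!is.null(bundle) &&
                   identical(bundle$templates[[id]], "groupII_D"))
        "GPI" else character()
      extractFeatures(id, model = model, seq = seq,
                      intron_count = intronCounts[id] %||% NA_real_,
                      clade_label = clades[id] %||% NA_character_,
                      annotations = annot)
    }, error = function(e) {
      log("gene ", id, " structure stage degraded: ", conditionMessage(e))
      degraded <<- c(degraded, id)
      extractFeatures(id, model = NULL, seq = NULL,
                      intron_count = intronCounts[id] %||% NA_real_,
                      clade_label = clades[id] %||% NA_character_)
    })
  }
  features <- do.call(rbind, rows)

  ## ---- stage: classification ------------------------------------------
  log("classifying ", nrow(features), " genes")
  cls <- classifyBatch(features)
  records <- cls$records

  intronStats <- if (!is.null(intronCounts)) {
    grp <- setNames(records$group, records$gene_id)
    groupAverage(intronCounts[names(intronCounts) %in% names(grp)], grp)
  } else NULL

  ## ---- outputs ---------------------------------------------------------
  hdr <- sprintf("# apclass run; seed=%d; config_hash=%s", seed, cfgHash)
  classesPath <- file.path(outdir, "classes.tsv")
  writeLines(c(hdr, paste(colnames(records), collapse = "\t"),
               do.call(paste, c(records, sep = "\t"))), classesPath)
  report <- list(seed = seed, config_hash = cfgHash,
                 n_genes = nrow(records),
                 counts = as.list(cls$counts),
                 degraded = degraded,
                 intron_means = if (!is.null(intronStats))
                   setNames(as.list(intronStats$mean_introns),
                            intronStats$group) else NULL)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(records = records, counts = cls$counts, intron_stats = intronStats,
       features = features, tree = tree, clades = clades,
       degraded = degraded, outdir = outdir, config_hash = cfgHash,
       status = if (length(degraded)) 3L else 0L)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
readFastaSeqs <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaSeqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
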