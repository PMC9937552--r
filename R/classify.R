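## Rule engine: combines clade, gene-structure, domain, motif and topology
## evidence into group I-IV and subgroup calls with an auditable evidence
## trail. Booleans are tri-state (TRUE/FALSE/NA); NA means unknown and never
## silently behaves as FALSE — a rule that needs a value that is unknown
## simply does not fire. Clade evidence dominates structural evidence (the
## groups are defined on the tree first; structure is confirmatory), unless
## precedence is inverted for structure-only studies.

#' Build a per-gene feature vector
#'
#' @param gene_id Gene identifier.
#' @param intron_count Introns (numeric; NA = unknown).
#' @param clade_label Group label from the tree ("I".."IV"; NA = no tree).
#' @param clade_subgroup Optional subgroup label from the tree (resolves the
#'   subgroup pairs that share a structural signature).
#' @param has_saposin,has_nap1,has_c_extend,very_long_c_extend,has_tm_helix,
#'   canonical_active_site Tri-state logicals.
#' @param n_bonds,nap1_bonds,cys_count,interdomain_strands Integer features
#'   (NA = unknown).
#' @param topology_string Canonical topology serialization (or NA).
#' @param lacking,extra,bond_labels Character vectors from the canonical
#'   topology (reference labels missing, insertion labels, bond label pairs
#'   like "C4-C6").
#' @param annotations External annotations (e.g. "GPI",
#'   "interdomain_helix"); never predicted here.
#' @param taxon Optional taxon label, recorded as evidence only.
#' @return A list of class "FeatureVector".
#' @export
featureVector <- function(gene_id,
                          intron_count = NA_real_,
                          clade_label = NA_character_,
                          clade_subgroup = NA_character_,
                          has_saposin = NA, has_nap1 = NA,
                          has_c_extend = NA, very_long_c_extend = NA,
                          has_tm_helix = NA, canonical_active_site = NA,
                          n_bonds = NA_integer_, nap1_bonds = NA_integer_,
                          cys_count = NA_integer_,
                          interdomain_strands = NA_integer_,
                          topology_string = NA_character_,
                          lacking = character(), extra = character(),
                          bond_labels = character(),
                          annotations = character(),
                          taxon = NA_character_) {
  structure(list(
    gene_id = as.character(gene_id), intron_count = intron_count,
    clade_label = clade_label, clade_subgroup = clade_subgroup,
    has_saposin = has_saposin, has_nap1 = has_nap1,
    has_c_extend = has_c_extend, very_long_c_extend = very_long_c_extend,
    has_tm_helix = has_tm_helix, canonical_active_site = canonical_active_site,
    n_bonds = n_bonds, nap1_bonds = nap1_bonds, cys_count = cys_count,
    interdomain_strands = interdomain_strands,
    topology_string = topology_string,
    lacking = lacking, extra = extra, bond_labels = bond_labels,
    annotations = annotations, taxon = taxon
  ), class = "FeatureVector")
}

isTrue <- function(x) isTRUE(as.logical(x))
isFalse <- function(x) isFALSE(as.logical(x))

## Structure-only group call; returns list(group, evidence).
structureGroup <- function(fv) {
  ev <- list()
  note <- function(rule, feature, value)
    ev[[length(ev) + 1L]] <<- data.frame(rule = rule, feature = feature,
                                         value = as.character(value))
  intronPoor <- !is.na(fv$intron_count) && fv$intron_count <= 2
  intronRich <- !is.na(fv$intron_count) && fv$intron_count >= 4
  group <- "unassigned"
  if (isFalse(fv$canonical_active_site) && intronPoor) {
    group <- "IV"
    note("noncanonical_site_intron_poor", "canonical_active_site", FALSE)
    note("noncanonical_site_intron_poor", "intron_count", fv$intron_count)
  } else if (isTrue(fv$has_saposin)) {
    group <- "I"
    note("saposin_domain", "has_saposin", TRUE)
  } else if (!is.na(fv$n_bonds) && fv$n_bonds == 3L && isFalse(fv$has_nap1)) {
    group <- "I"
    note("three_bond_core_no_nap1", "n_bonds", 3L)
  } else if (isTrue(fv$has_nap1) && intronRich) {
    group <- "II"
    note("nap1_intron_rich", "has_nap1", TRUE)
    note("nap1_intron_rich", "intron_count", fv$intron_count)
  } else if (isTrue(fv$has_nap1) && intronPoor) {
    group <- "III"
    note("nap1_intron_poor", "has_nap1", TRUE)
    note("nap1_intron_poor", "intron_count", fv$intron_count)
  }
  list(group = group, evidence = ev)
}

#' Assign the family group (I-IV) from a feature vector
#'
#' Rule order: a clade label wins when present (structure is then
#' confirmatory; a clade/structure conflict keeps the clade call, downgrades
#' confidence and logs the conflict). Without a clade label the structural
#' rules apply: non-canonical active site + intron-poor is group IV; a
#' saposin-like domain, or a three-bond core without NAP1 fold, is group I;
#' NAP1 fold + intron-rich (>= 4) is group II; NAP1 fold + intron-poor
#' (<= 2) is group III; otherwise unassigned. The intron cutoffs are derived
#' from the family's strongly bimodal group averages.
#'
#' @param fv A \code{\link{featureVector}}.
#' @param cladeDominates Set FALSE to let structure outrank the clade label
#'   (structure-only studies).
#' @return list(gene_id, group, subgroup = "none", evidence (data.frame),
#'   confidence) of class "ClassificationRecord".
#' @export
assignGroup <- function(fv, cladeDominates = TRUE) {
  stopifnot(inherits(fv, "FeatureVector"))
  sg <- structureGroup(fv)
  ev <- sg$evidence
  note <- function(rule, feature, value)
    ev[[length(ev) + 1L]] <<- data.frame(rule = rule, feature = feature,
                                         value = as.character(value))
  haveClade <- !is.na(fv$clade_label)
  if (haveClade && cladeDominates) {
    group <- fv$clade_label
    note("clade_label", "clade_label", fv$clade_label)
    if (sg$group == "unassigned") confidence <- "clade-only"
    else if (sg$group == group) confidence <- "clade+structure"
    else {
      confidence <- "clade-only"
      note("conflict", "structure_group", sg$group)
    }
  } else if (sg$group != "unassigned") {
    group <- sg$group
    confidence <- if (haveClade) {
      if (fv$clade_label == sg$group) "clade+structure" else "structure-only"
    } else "structure-only"
  } else if (haveClade) {
    group <- fv$clade_label
    confidence <- "clade-only"
    note("clade_label", "clade_label", fv$clade_label)
  } else {
    group <- "unassigned"
    confidence <- "structure-only"
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(rule = character(), feature = character(), value = character())
  structure(list(gene_id = fv$gene_id, group = group, subgroup = "none",
                 evidence = evidence, confidence = confidence),
            class = "ClassificationRecord")
}

#' Assign the subgroup given a group-level record
#'
#' Decision table over saposin presence (I-A vs I-B), C-extension length
#' class and GPI annotation (II-A..II-D), and topology deltas against the
#' reference numbering (III-A..III-G, with the structure-sharing pairs
#' III-C/III-D and III-B/III-G left explicitly ambiguous unless the tree
#' supplies a subgroup). Group IV has no subdivision and is recorded as
#' "IV".
#'
#' @param record A "ClassificationRecord" from \code{\link{assignGroup}}.
#' @param fv The same gene's \code{\link{featureVector}}.
#' @return The record with subgroup (and possibly confidence) updated.
#' @export
assignSubgroup <- function(record, fv) {
  stopifnot(inherits(record, "ClassificationRecord"))
  ev <- record$evidence
  note <- function(rule, feature, value)
    ev <<- rbind(ev, data.frame(rule = rule, feature = feature,
                                value = as.character(value)))
  sub <- "none"
  ambiguous <- FALSE
  g <- record$group
  if (g == "I") {
    if (isTrue(fv$has_saposin)) { sub <- "I-A"; note("I_saposin", "has_saposin", TRUE) }
    else if (isFalse(fv$has_saposin)) { sub <- "I-B"; note("I_no_saposin", "has_saposin", FALSE) }
  } else if (g == "II") {
    if ("GPI" %in% fv$annotations) { sub <- "II-D"; note("II_gpi", "annotations", "GPI") }
    else if (isTrue(fv$very_long_c_extend)) { sub <- "II-C"; note("II_very_long_c_extend", "very_long_c_extend", TRUE) }
    else if (isTrue(fv$has_c_extend)) { sub <- "II-B"; note("II_c_extend", "has_c_extend", TRUE) }
    else if (isFalse(fv$has_c_extend)) { sub <- "II-A"; note("II_no_c_extend", "has_c_extend", FALSE) }
  } else if (g == "III") {
    lack <- fv$lacking; bonds <- fv$bond_labels
    if (all(c("C4", "C5") %in% lack) || "C9a-C11a" %in% bonds) {
      sub <- "III-G"
      note("III_G_variant_topology", "topology",
           paste(c(intersect(c("C4", "C5"), lack),
                   intersect("C9a-C11a", bonds)), collapse = ","))
    } else if ((!is.na(fv$nap1_bonds) && fv$nap1_bonds >= 3L) ||
               (!is.na(fv$cys_count) && fv$cys_count >= 14L)) {
      sub <- "III-A"
      note("III_A_14cys_triple_nap1", "nap1_bonds", fv$nap1_bonds)
    } else if (all(c("C2", "C3") %in% lack)) {
      sub <- if (!is.na(fv$clade_subgroup) &&
                 fv$clade_subgroup %in% c("III-C", "III-D")) fv$clade_subgroup
             else { ambiguous <- TRUE; "III-C|III-D" }
      note("III_lacks_C2_C3", "lacking", "C2,C3")
    } else if (length(bonds) && !"C4-C6" %in% bonds &&
               !"C4" %in% lack && !"C6" %in% lack) {
      sub <- "III-F"
      note("III_F_lacks_C4_C6_bond", "bond_labels", "no C4-C6")
    } else if ("interdomain_helix" %in% fv$annotations) {
      sub <- "III-E"
      note("III_E_interdomain_helix", "annotations", "interdomain_helix")
    } else if (length(bonds)) {
      sub <- if (!is.na(fv$clade_subgroup) &&
                 fv$clade_subgroup %in% c("III-B", "III-G")) fv$clade_subgroup
             else { ambiguous <- TRUE; "III-B|III-G" }
      note("III_baseline_topology", "topology_string",
           ifelse(is.na(fv$topology_string), "", fv$topology_string))
    }
  } else if (g == "IV") {
    sub <- "IV"
    note("IV_no_subdivision", "group", "IV")
  }
  record$subgroup <- sub
  record$evidence <- ev
  if (ambiguous) record$confidence <- paste0(record$confidence, "/ambiguous")
  record
}

#' Classify a batch of genes
#'
#' @param features A data.frame with one row per gene; columns are the
#'   scalar \code{\link{featureVector}} fields, with the vector-valued
#'   fields (\code{lacking}, \code{extra}, \code{bond_labels},
#'   \code{annotations}) as comma-separated strings.
#' @param cladeDominates Passed to \code{\link{assignGroup}}.
#' @return list(records = data.frame(gene_id, group, subgroup, confidence),
#'   evidence = per-gene evidence list, counts = per-group table).
#'   Deterministic: identical feature tables give identical outputs.
#' @export
classifyBatch <- function(features, cladeDominates = TRUE) {
  if (nrow(features) == 0L)
    return(list(records = data.frame(gene_id = character(), group = character(),
                                     subgroup = character(), confidence = character()),
                evidence = list(), counts = table(character())))
  if (anyDuplicated(features$gene_id))
    stop("duplicate gene_id: ",
         features$gene_id[duplicated(features$gene_id)][1L], call. = FALSE)
  splitCsv <- function(x) if (is.na(x) || !nzchar(x)) character() else
    strsplit(x, ",", fixed = TRUE)[[1]]
  records <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    row <- features[i, , drop = FALSE]
    get <- function(col, default) if (col %in% names(row)) row[[col]] else default
    fv <- featureVector(
      gene_id = row$gene_id,
      intron_count = get("intron_count", NA_real_),
      clade_label = get("clade_label", NA_character_),
      clade_subgroup = get("clade_subgroup", NA_character_),
      has_saposin = get("has_saposin", NA),
      has_nap1 = get("has_nap1", NA),
      has_c_extend = get("has_c_extend", NA),
      very_long_c_extend = get("very_long_c_extend", NA),
      has_tm_helix = get("has_tm_helix", NA),
      canonical_active_site = get("canonical_active_site", NA),
      n_bonds = get("n_bonds", NA_integer_),
      nap1_bonds = get("nap1_bonds", NA_integer_),
      cys_count = get("cys_count", NA_integer_),
      interdomain_strands = get("interdomain_strands", NA_integer_),
      topology_string = get("topology_string", NA_character_),
      lacking = splitCsv(get("lacking", NA_character_)),
      extra = splitCsv(get("extra", NA_character_)),
      bond_labels = splitCsv(get("bond_labels", NA_character_)),
      annotations = splitCsv(get("annotations", NA_character_)),
      taxon = get("taxon", NA_character_)
    )
    records[[i]] <- assignSubgroup(assignGroup(fv, cladeDominates), fv)
  }
  recDf <- data.frame(
    gene_id = vapply(records, `[[`, character(1), "gene_id"),
    group = vapply(records, `[[`, character(1), "group"),
    subgroup = vapply(records, `[[`, character(1), "subgroup"),
    confidence = vapply(records, `[[`, character(1), "confidence"),
    stringsAsFactors = FALSE
  )
  list(records = recDf,
       evidence = setNames(lapply(records, `[[`, "evidence"), recDf$gene_id),
       counts = table(factor(recDf$group,
                             levels = c("I", "II", "III", "IV", "unassigned"))))
}
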