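---
title: "Structure-informed classification of plant A1 aspartic proteases: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-informed classification of plant A1 aspartic proteases: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apclass)
```

## The problem

Plant A1 (pepsin-like) aspartic proteases are numerous and structurally
heterogeneous: beyond the bilobed pepsin fold they differ in whether they
carry a saposin-like vacuolar-targeting insert, a nepenthesin-type (NAP1)
disulfide-stabilised surface loop, a C-terminal extension, a transmembrane
prosegment, a GPI anchor, and in whether their catalytic tetrads are the
canonical D[TS]G[ST] pair at all. Sequence-only classifications of this
family have been unstable. A robust scheme combines three lines of
evidence: clade membership on a family tree, exon–intron architecture
(groups I and II are intron rich, about 8–10 introns on average; groups III
and IV essentially intron poor), and structural fingerprints read from
predicted models — above all the disulfide-bond topology expressed in a
canonical cysteine numbering (C1..C12, with insertion codes such as C6a for
extra cysteines and "lacking" records for absent ones).

`apclass` implements that combination as a tested pipeline: structure
parsing, geometric disulfide detection, canonical topology labelling,
sequence-guided rigid superposition, domain/motif annotation, an iterative
PSSM homology search, entropy-trimmed neighbor-joining trees with anchor
clade labelling, GFF3 intron statistics, and a rule engine that merges the
evidence into group I–IV and subgroup calls with an auditable trail.

## Disulfide topologies

Bond detection is geometric: cysteine pairs whose SG atoms lie within a
threshold are candidates, and the reported set is the maximum-cardinality
matching minimising total SG–SG distance (ties broken by smallest residue
pair). The default threshold is **2.5 Å** — the covalent S–S bond is about
2.05 Å and the slack absorbs predicted-model coordinate error; it is a
tunable argument. The matching rule is deliberately simple enough to check
against exhaustive enumeration, which the test suite does for every fixture
with up to eight cysteines. Bonds involving residues with pLDDT < 50 are
flagged rather than dropped, since low-confidence regions still carry
topological signal.

Topology labels transfer from a reference protein by global alignment
(Needleman–Wunsch, BLOSUM62, gap open 10 / extend 0.5): a query cysteine
aligned to a reference cysteine inherits its base label; any other query
cysteine becomes an insertion (C6a, C9b, …) on the preceding base label;
uninherited reference labels are reported as lacking. The conventional
references are the Marchantia group-II protease (written "mp4g19220" here;
the literature spells this identifier inconsistently, and we document
rather than resolve the discrepancy), ASPR1 for groups III/IV, and APA1 for
group I. Because the true sequences of these proteins cannot be shipped,
the package constructs **synthetic stand-in references**: deterministic
scaffold sequences with cysteines at fixed positions wired with the
group-typical topology (group II/III: C1-C8, C2-C3, C4-C6, C5-C7, C9-C12,
C10-C11; group I: C1-C2, C3-C4, the saposin triple C5-C10/C6-C9/C7-C8, and
C11-C12). Label transfer is exact for scaffold-derived queries and
approximate for arbitrary ones — a stated limitation, not a hidden one.

## Superposition

`kabsch()` is the closed-form least-squares rigid fit (SVD of the
covariance of the centred point sets, reflection corrected), and
`superposeModels()` wraps it in the sequence-guided, outlier-rejecting
iteration that structure viewers call "align": build the residue
correspondence from a global sequence alignment restricted to
Cα-bearing match columns, fit, drop pairs deviating by more than the
cutoff, refit. Defaults are **5 cycles and a 2.0 Å per-pair cutoff** with
BLOSUM62 (10/0.5) and Cα atoms only; the published pairwise RMSD values
this reproduces were generated by a viewer whose parameters are not stated,
so the defaults mirror common viewer behaviour, are all overridable, and
the reproduction tolerance is held at the acceptance level rather than
pretended to be exact. RMSD is reported over retained pairs, with the
pre-rejection value kept alongside. Degenerate (rank-deficient) point sets
are flagged; an independent grid-search minimisation over Euler angles and
the least-squares fit in `bio3d` serve as cross-checks in the tests.

## Domains and motifs

* **Active sites.** First D[TS]G[ST] occurrence in each sequence half; a
  half without one falls back to the first D-x-G-x tetrad, then to reading
  the 4-mer aligned to a reference's motif columns. The call is canonical
  only if both motifs match D[TS]G[ST]; a group-IV (SAP1-like) sequence
  yields DLGG/SSVN with `canonical = FALSE`. The alignment fallback is what
  makes a motif like SSVN — which matches no D-x-G-x pattern — readable at
  the position homologous to the second tetrad.
* **Transmembrane helices.** Kyte–Doolittle hydropathy, window 19, mean ≥
  1.6, merged maximal windows. Windows of these sizes are the classic TM
  scan; the boundary arithmetic is hand-checked in the tests.
* **Saposin-like domain.** Three nested disulfides over six consecutive
  cysteines (a-f, b-e, c-d), detected by a sliding window over the
  cysteine list.
* **NAP1 fold.** Present when at least one bond has both ends on canonical
  labels C4–C7 (insertions included); the bond count distinguishes
  III-A-style triple stabilisation from the single-bond variants.
* **C-terminal extension.** ≥ 40 residues beyond the last core
  disulfide-bearing cysteine; "very long" at ≥ 120. The 40/120 cutoffs are
  package choices calibrated on the family's architectures (short
  extensions vs the dramatically extended II-C proteins).
* **Interdomain strands.** Cα-only secondary structure (predicted models
  carry no hydrogens, so hydrogen-bond-based assignment is unavailable): a
  residue is extended when d(Cαi, Cαi+2) ≥ 6.0 Å (ideal strand ≈ 6.5 Å,
  helix ≈ 5.5 Å), a strand is ≥ 3 consecutive extended residues. Whether
  the II-D "eight" refers to strands or sheets is ambiguous in the source
  material; the package counts strands and records the ambiguity.
* **Signal peptide / propeptide.** Accepted as curated annotations when
  supplied; otherwise a simple hydrophobic-window heuristic (explicitly a
  heuristic, not a predictor — external predictors are out of scope).

## Profile search

The family-identification procedure is two-round: a seed profile finds a
first hit set, the profile is rebuilt from the hit windows, and the search
runs again; the rebuilt profile recovers divergent members the seed misses
(the historical example being SAP1/SAP2, which a stock domain profile
failed to find). The profile is a **PSSM** — per-column log-odds in bits
with Dirichlet-style pseudocounts (default weight 0.1) against
Robinson–Robinson background frequencies, columns with > 50% gaps dropped —
not a full profile HMM: the two-round logic is the contribution preserved
here, and reproducing Plan7 scoring is a non-goal. Hits are best ungapped
windows; the default threshold is 60% of the profile self-score (no
E-value machinery). Hit windows are profile-anchored and therefore mutually
aligned, which is what makes the round-2 rebuild well-defined without an
MSA program.

## Trees and clade labels

Alignment trimming is normalised Shannon column entropy (H / log2 20, in
[0,1]) with a gap-fraction filter, cutoff defaulting to **0.8** inside the
conventional 0.7–0.9 window for this family's alignments. This is a
simplified stand-in for BMGE-style trimming: the BLOSUM-similarity
smoothing of the original is not reproduced, and the stand-in is labelled
as such. Distances are p-distances (optionally Poisson-corrected) with
pairwise gap deletion; the tree is neighbor joining via `ape::nj` with
negative branch estimates clamped to zero. The classification consumes
clade membership, not likelihoods, which is why NJ replaces
maximum-likelihood inference here; an externally computed tree (e.g. an ML
tree with 1000 bootstraps) can be supplied to the pipeline instead. NJ
tie-breaking follows `ape`'s deterministic internal order rather than an
explicit index rule; determinism for fixed input is what the pipeline
needs and what the tests pin. Bootstrap (default 100 replicates,
configurable to 1000) resamples kept columns and reports bipartition
frequencies. Clade labels propagate from anchor leaves: each leaf walks
toward the root of the midpoint-rooted tree until a clade containing
anchors is found, takes their label if they agree, and stays "unassigned"
otherwise.

## The rule engine

Group rules, in order: a clade label wins when present (structure then
confirms or conflicts; conflicts keep the clade call, downgrade confidence
and are logged — the groups are defined on the tree first, and a flag can
invert the precedence for structure-only studies). Without a clade label:
non-canonical active site + intron-poor → IV; saposin-like domain, or a
three-bond core without NAP1 fold → I; NAP1 + intron-rich (≥ 4) → II;
NAP1 + intron-poor (≤ 2) → III. The intron cutoffs 4/2 are derived
package choices reflecting the family's strongly bimodal group averages
(about 10.3/8.5 vs 0.45/0.33), not literature statements. All booleans are
tri-state; unknown never acts as false, so missing evidence makes rules
abstain rather than misfire.

Subgroups: I splits on the saposin domain (I-A with, I-B without); II on
GPI annotation (II-D), very long C-extension (II-C), any C-extension
(II-B), else II-A; III on topology deltas — lacking C4+C5 with the extra
C9a-C11a bond → III-G variant, three NAP1 bonds / 14 cysteines → III-A,
lacking C2-C3 → III-C/III-D, missing C4-C6 bond with both cysteines
present → III-F, an extra interdomain helix (annotation evidence) → III-E,
baseline ASPR1-like topology → III-B/III-G. The pairs III-C/III-D and
III-B/III-G share a structural signature and are resolved **only** by the
tree; structure-only input yields an explicitly ambiguous call
("III-C|III-D", confidence suffixed "/ambiguous") — the engine refuses to
over-commit. Group IV is not subdivided. Species-distribution regularities
(e.g. I-B restricted to Brassicaceae) are recorded as evidence when a
taxon is supplied, never enforced as rules.

## The synthetic study

Every stage is validated against generated data with known truth; nothing
is downloaded. The generator defines the study conditions:

* **Structures.** Cα atoms along a wide spiral (3.8 Å spacing,
  non-neighbours well separated); bonded SG pairs placed exactly 2.05 Å
  apart on a radial ray, unbonded SG 1.8 Å outward; per-subgroup topology
  templates implement the architectures described above (including the
  saposin insert, the APCB1-style prosegment with a planted TM stretch,
  and the II-C extension with its disulfide-containing sub-fold). Jitter
  sigma is the **RMS total displacement per atom** (per-component sd
  sigma/√3); 0.2 Å is the mild-error regime used in the recovery study.
  Geometry is idealised, not physically relaxed — downstream operations
  consume distances and segment patterns only.
* **Families.** Four clades joined by long stems (0.45 substitutions/site),
  within-clade branch lengths 0.02–0.12, evolved from a shared
  protease-core root under a single-rate Jukes–Cantor-style amino-acid
  model, no indels (so the output is a ready-made alignment of width 450).
  Catalytic motifs and cysteines are held fixed; the group-IV lineage
  carries DLGG/SSVN. Group proportions default to the family-census
  proportions (90:275:682:153).
* **Gene models.** GFF3 gene/mRNA/exon hierarchies with intron counts
  drawn from group-typical pools (I: 9–12, II: 7–10, III/IV: 0–1),
  exon lengths 100–300, intron lengths 80–400.

What passing synthetic tests shows — and what it does not: the pipeline's
operations are correct on data matching their assumptions (rigid
geometry, alignable scaffolds, clean clades). Real predicted models have
correlated, region-dependent error; real families have indels, domain
gains/losses and annotation noise. The synthetic study validates the
machinery, not the biology of any particular genome.

## Numerical choices and degenerate inputs

Determinism throughout: all generators take a seed and restore the
caller's RNG state; identical configurations give identical outputs, and
each run records a config hash. Half-up rounding (2 decimals) for group
intron means, since base R rounds half-even. Empty/degenerate inputs have
defined behaviour: a model without cysteines yields an empty bond set (not
an error); all-gap columns have entropy 1 (removable); fully trimmed
alignments error with advice; fewer than three retained superposition
pairs errors with diagnostics; one gene's failed structure stage marks the
gene degraded without aborting the batch.

Problem sizes in the shipped tests and acceptance script — 100-replicate
recovery studies, 100 random 8-taxon trees, a 200-gene end-to-end run,
1000 shuffled decoys — are the package's standard desk-scale study
conditions; all are arguments, and larger runs only cost time.

## Known limitations

* The published pairwise RMSDs and exemplar disulfide sets can only be
  reproduced against the actual predicted models and the experimental
  pepsin structure; those files are not redistributable here, so the
  corresponding acceptance checks fail visibly until a structure directory
  is supplied (`options(apclass.structure_dir = ...)`).
* Reference numberings ship as synthetic stand-ins (see above).
* The II-C-specific motif is defined in the source material only by a
  figure; it is implemented as "a disulfide-containing compact sub-fold
  within the C-extension" and recorded as not fully reconstructable.
* Pseudogene/misannotation curation has no stated rule; candidates
  (truncated core, no motifs, few cysteines) are flagged, never
  auto-dropped.
* mmCIF input, GPI-anchor and subcellular-location prediction, and
  maximum-likelihood tree inference are out of scope.
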