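Package: apclass
Title: Structure-Informed Classification of Plant A1 Aspartic Proteases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies plant A1 (pepsin-like) aspartic proteases into
    groups I-IV and their subgroups by combining disulfide-bond topology
    fingerprints derived from predicted structure models, sequence-guided
    rigid-body superposition, domain-architecture annotation (saposin-like
    insert, NAP1 fold, C-terminal extension, transmembrane helix), iterative
    position-specific scoring matrix homology search, entropy-trimmed
    neighbor-joining phylogenies, and GFF3 intron statistics. Ships a
    deterministic synthetic-data generator (structures with planted disulfide
    bonds, sequence families evolved along known trees, gene models with known
    exon counts) so that every stage is testable without downloads, and an
    end-to-end pipeline with an auditable per-gene evidence trail.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phangorn,
    bio3d,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
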