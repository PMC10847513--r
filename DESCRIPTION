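Package: eddscreen
Title: Motif-Based Screening for the Entner-Doudoroff Pathway and Its
    Dehydratase
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to discriminate 6-phosphogluconate dehydratases (EDD)
    from their paralogs, the dihydroxy-acid dehydratases (DHAD), using
    diagnostic consensus motifs derived from multiple sequence
    alignments; to call per-genome Entner-Doudoroff pathway completeness
    from EDD/EDA gene co-occurrence; to flag putative eukaryotic EDD
    hits as bacterial sequencing artefacts via codon usage, gene
    structure and phylogenetic placement; to build neighbor-joining
    trees with bootstrap supports and test monophyly and lateral-
    gene-transfer interspersion by Fitch parsimony; and to fit
    Michaelis-Menten kinetics and standard-addition quantification with
    detection limits. A synthetic-data module generates every input
    with planted ground truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
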