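Package: protsig
Title: Presence/Absence Protein Signatures and Ubiquitin Homeostasis Scoring
    for Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking a behavioral phenotype to hippocampal
    proteome composition in a three-cohort label-free proteomics design.
    Computes relative escape latency (REL3) from Barnes-maze trials and
    classifies spatial-memory phenotype; applies replicate-based protein
    presence filters (two-of-three technical replicates, >66% of biological
    replicates, SEM-vs-mean quality filter, unit-AUC sentinel for undetected
    cohorts); partitions cohort protein sets into named presence/absence
    signatures with fold-change and Wilcoxon-Mann-Whitney regulation calls;
    screens Gene Ontology processes with a percentage-based inclusion
    criterion; and intersects signatures with a ubiquitin-proteasome system
    reference to compute a signed ubiquitin homeostasis score. Includes a
    synthetic-data generator with planted ground truth so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
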