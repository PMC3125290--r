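Package: mitoclock
Title: Lineage-Aware Molecular-Clock Dating of Mitochondrial Haplogroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying mutation-rate heterogeneity across human
    mitochondrial DNA haplogroups and its consequences for coalescence
    dating. Provides synonymous/non-synonymous substitution classification
    under the vertebrate mitochondrial genetic code, per-haplotype
    phylogenetic distance profiles on mutation-annotated haplogroup trees,
    Poisson accumulation tests, rho-statistic dating with anchored and
    clade-recalibrated clocks, counting-based branch dN/dS contrasts,
    HVS1 sequence-quality metrics, and a coalescent simulator with
    lineage-specific rate multipliers, selection, and haplogroup-based
    ascertainment sampling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
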