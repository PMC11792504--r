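Package: metapel
Title: Metaproteomic Profiling of Gut Microbiome Response to a Prebiotic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for metaproteomic analysis of gut-microbiome response
    to a dietary intervention, starting from a peptide-evidence table. Retains
    strain-specific peptides, quantifies protein expression levels (PELs) as
    maximum peptide intensity, rolls PELs up a strain-level taxonomy, computes
    alpha/beta diversity with PERMANOVA, tests differential abundance of taxa
    and proteins with negative-binomial likelihood-ratio tests and
    empirical-Bayes fold-change shrinkage, performs directional KEGG-orthology
    pathway enrichment, and integrates abundant species with targeted
    orthologs into cooperative metabolic route networks. Includes a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    igraph,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
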