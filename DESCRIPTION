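Package: metapro
Title: Metaproteomic Protein-Subgroup Inference, Spectral-Count
    Quantification and Strict-Dominance Biomarker Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-identification analysis of shotgun metaproteomics data
    from clinical microbiome studies. Groups proteins identified by the
    same set of peptides into subgroups ("metaproteins") under the
    principle of parsimony, quantifies each subgroup by the sum of the
    spectral counts of its specific peptides, derives consensus
    taxonomic and KEGG Orthology annotations per subgroup, computes
    fresh/frozen replicate-concordance and diversity statistics, and
    screens for candidate biomarkers that are strictly over- or
    under-represented in every sample of one clinical group relative to
    every sample of another.  A ground-truthed synthetic-data generator
    (protein catalogue, in silico tryptic digestion, negative-binomial
    spectral counts, planted biomarkers) makes every stage testable
    without access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
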