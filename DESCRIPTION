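Package: cystflow
Title: Spectral-Count Differential Proteomics for Sequential Cystic-Fluid Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free differential proteomics of repeated biofluid samples
    quantified by spectral counting. Implements total-signal normalization of
    run-level spectral counts, replicate averaging into per-sample master
    protein lists, presence/absence Venn partitioning across tumor histotypes,
    selection of highly reproducible (HR) proteins, differential calling with
    the DAve and DCI indexes, relative-abundance up/down representation with
    per-pathway bubble summaries, hypergeometric overrepresentation analysis
    with Benjamini-Hochberg correction, protein-protein interaction edge
    filtering and node annotation, replicate-stability statistics (Levene and
    one-way ANOVA, chi-square homogeneity), and a synthetic study generator
    with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    igraph,
    car
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    knitr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, DifferentialExpression, Network
RoxygenNote: 7.3.3
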