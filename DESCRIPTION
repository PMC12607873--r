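Package: hmaFidelity
Title: Ecological Fidelity Analysis of Human Microbiota-Associated Mice
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how faithfully human microbiota-associated (HMA)
    mice reproduce the gut ecology of their human stool donors. Provides
    per-taxon percent-engraftment statistics with high/medium/low
    stratification, from-scratch Bray-Curtis dissimilarity, principal
    coordinate analysis, PERMANOVA and PERMDISP permutation tests,
    donor-recipient delta-abundance concordance and Fisher-z correlation
    comparisons, together with a synthetic donor/recipient cohort generator
    (a parametric host-filter model with truth sidecars) so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
biocViews: Microbiome, Metagenomics, Software, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
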