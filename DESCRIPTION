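Package: embryodiv
Title: Comparative Analysis of Sex-Biased and Maternal Gene Expression in
    Drosophila Blastoderm Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for comparative transcriptomics of early Drosophila
    embryos across four species: anchored percentile/TMM/quantile
    normalization of FPKM matrices, rank-quantile classification of
    sex-biased genes with Muller-element enrichment tests, Brownian-motion
    phylogenetic variance of expression with bootstrap faster-X tests,
    correspondence analysis with supplementary projection of pooled
    samples, SVM classification of maternal versus zygotic transcript
    origin, and a kinetic model of maternal mRNA degradation with
    likelihood-ratio selection of species-specific rates. Includes a
    synthetic-data generator with full ground truth emulating the design
    of a four-species single-embryo study.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    e1071,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
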