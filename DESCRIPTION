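Package: fracdex
Title: Fractionation-Aware Differential Expression and Nuclear-Export
    Analysis for Paired Whole-Cell/Cytoplasmic Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for subcellular-fractionation RNA-seq
    experiments comparing disease and treatment conditions across paired
    whole-cell and cytoplasmic transcriptomes.  Provides count filtering,
    relative-log-expression (RLE) normalisation, negative-binomial
    dispersion estimation with empirical-Bayes shrinkage, quasi-likelihood
    differential-expression testing, one-way ANOVA testing for continuous
    expression matrices, a simplified differential exon-usage test,
    classification of transcripts with altered nuclear export from the
    intersection of cytoplasmic and whole-cell fold changes, extraction of
    disease-modifying expression signatures with reversal analysis,
    cross-species ortholog direction-concordance analysis, sequencing
    coverage and multidimensional-scaling diagnostics, and a truth-labelled
    synthetic-data generator emulating a two-genotype, two-treatment,
    two-fraction design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
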