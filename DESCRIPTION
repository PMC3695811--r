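Package: senscall
Title: Calibrating SNV Detection Sensitivity from Read Depth in Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("senscall", "developers", email = "senscall@example.org", role = c("aut", "cre"))
Description: Quantifies single-nucleotide-variant (SNV) detection sensitivity
    as a function of read depth in targeted (exome-style) sequencing.
    Provides interval algebra and readers/writers for SAM, BED, VCF, FASTA
    and bedGraph; a synthetic exome-capture simulator with per-tile capture
    efficiency heterogeneity, G+C-linked bias, sequencing error and
    reference-allele capture bias; read-pair-preserving random down-sampling;
    a diploid genotype-likelihood caller; estimation of genotype-specific
    sensitivity-by-depth curves against a gold-standard truth set, including
    a naive binomial comparison; and application of calibration tables to
    score arbitrary genomic partitions (base, exon, gene, exome) for
    expected missed variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
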