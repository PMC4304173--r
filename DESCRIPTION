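Package: txmapr
Title: Integrated Differential Transcriptome Maps from Multi-Platform Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates probe-level expression samples from heterogeneous
    microarray platforms into per-condition pooled transcriptome maps and
    compares two conditions along the genome. Samples are linearized,
    cleaned of non-positive signal, intra-sample normalized as percentage
    of the mean and inter-sample normalized by scaled quantile
    normalization; per-locus pooled means are compared as ratios, extreme
    loci flagged at the 2.5th percentile tails, and sliding 500 kb genomic
    segments (250 kb shift) called over- or under-expressed by a
    hypergeometric enrichment test with multiple-testing correction.
    Single-gene maps, chromosome-level median dosage ratios, ranked gene
    lists, and a fully seeded synthetic-data generator with ground truth
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
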