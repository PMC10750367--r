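Package: bsaqtl
Title: QTL-seq Bulked-Segregant Analysis with Dual Parental Consensus Orientations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for QTL-seq (whole-genome bulked-segregant) mapping of
    quantitative traits in biparental recombinant inbred line (RIL)
    populations, modelled on the mapping of seed lignan content in sesame.
    Simulates F7 RIL populations under single-seed descent with a planted
    QTL truth model and emits parent/bulk VCFs; filters variants and
    polarizes bulk allele depths to either parental consensus orientation;
    computes per-site SNP/InDel-index, delta-index, sliding-window averages
    and Monte-Carlo confidence bands under the no-QTL null; calls candidate
    QTL regions, intersects them across the two orientations and names
    major QTLs; mines fully bulk-biased ("counter") variants inside QTL
    regions and classifies their gene-model effects; and quantifies
    single-locus and stacked allele effects on the phenotype.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
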