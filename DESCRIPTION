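Package: autozyg
Title: Autozygosity Mapping and Homozygous Variant Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) from SNP genotype panels with a
    PLINK-style scanning-window algorithm, selects subjects whose long-ROH burden
    indicates recent inbreeding, tiers homozygous exonic variants inside ROHs
    through a low-frequency-functional (LFF), damaging (LFF-D) and best-candidate
    filtration cascade, and tests candidate gene lists for enrichment against
    disease gene sets with permutation, interval-relocation and hypergeometric
    tests. Includes a synthetic-data generator that implants autozygous segments
    and annotated rare homozygous variants with full ground truth, so the whole
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
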