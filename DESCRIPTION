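Package: coexmeta
Title: Consensus Co-Expression Network and Gene-Level Meta-Analysis of
    Paired Intervention Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrated gene-level and network-level meta-analysis of
    multiple independent expression studies with paired pre/post designs,
    as used to contrast skeletal-muscle disuse and resistance-exercise
    transcriptome responses. Implements empirical-Bayes moderated paired
    t-tests combined across studies by Stouffer's method with
    Benjamini-Hochberg control; signed weighted co-expression networks
    with soft-threshold selection by the scale-free topology criterion,
    topological overlap, single-quantile calibration and parallel-minimum
    consensus; average-linkage module detection with eigengene merging;
    eigengene-level differential-regulation meta-analysis; rank-rank
    hypergeometric overlap (RRHO) for concordant and discordant gene
    sets; consensus module-membership hub selection; and generic
    over-representation analysis against GMT gene-set collections. A
    seeded multi-study simulator with planted modules and planted
    effects supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
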