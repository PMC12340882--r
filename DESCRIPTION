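Package: easyregions
Title: Sample-Agnostic Easy Regions for Short-Read Variant Calling from
    Pangenome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives sample-agnostic "easy regions" for short-read variant
    calling from a collection of genome assemblies. Reference k-mers sampled
    on a stride are classified as sufficiently unique by counting end-to-end
    alignments within bounded edit distance against the reference and against
    the whole pangenome; failing k-mer footprints are masked, an exact
    Hamming-distance mappability check rescues sampling misses, and regions
    shorter than a minimum length are dropped to give a lenient region set.
    Low-complexity regions detected with the symmetric DUST algorithm are
    additionally excluded to give a strict subset. Includes complete and
    seeded (pigeonhole) all-hits search engines, BED interval algebra, a
    synthetic pangenome simulator with planted features and exact truth
    labels, and region-restricted evaluation statistics (coverage, variant
    density, site-level FDR/FNR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    IRanges,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
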