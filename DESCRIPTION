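Package: featherkit
Title: Feather Rachis Morphometry, Splice-Consequence Prediction, and
    Two-Point Linkage Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of feather rachis shape from dorsal-view
    photographs via arc-length tangent-angle profiles theta(s), including
    backbone (midline) extraction, kink detection, bilateral mirror-symmetry
    and profile-dispersion statistics; prediction of the transcript and
    protein consequence of genomic deletions that destroy a splice donor,
    through cryptic donor-site activation, as in the frizzle (KRT75) chicken
    allele; and exact two-point linkage LOD scores, Mendelian-consistency
    checks and haplotype-sharing analysis for small loop-free pedigrees.
    Ships seedable synthetic-data generators (feather images, gene models,
    mapping crosses) with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Biostrings,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
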