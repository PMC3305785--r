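Package: rtms
Title: Genome-Wide Census of Retrotransposon-Associated Minisatellite Arrays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Locates all approximate copies of a set of minisatellite monomer
    consensus families in genome sequences, resolves cross-family matches into
    a unique hit set, clusters hits into discrete loci, attributes loci to
    annotated transposable elements by coordinate containment or to element
    families by flanking-sequence similarity, decomposes the interleaved
    tandem-array structure of each locus (units such as [ABAC]n), profiles
    per-family sequence and length variation, and summarizes the census as
    per-family tables and windowed genome density tracks. Includes a
    synthetic-genome generator that plants element-embedded and orphan
    minisatellite arrays with known ground truth so the whole pipeline can be
    validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
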