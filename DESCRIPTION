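Package: chromArch
Title: Genome Architecture Analysis for Chromosome-Scale Yeast Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the architecture of chromosome-scale
    fungal genome assemblies: contiguity and composition statistics (N50/L50,
    auN, GC, gap density), regional centromere identification by AT-bias
    sliding windows with Levan arm-ratio morphology classification and
    point-centromere motif screening, LTR retrotransposon candidate detection
    with paired-LTR divergence dating, inverted-repeat (palindrome) detection
    and cassette encapsulation analysis, intron extraction with GT-AG splice
    site validation, and intergenic splice-bridge classification from STAR
    splice junctions. Includes a synthetic genome simulator that plants
    centromeres, LTR elements, intron-bearing genes and palindromic cassettes
    with a ground-truth registry, so every analysis stage can be benchmarked
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, Alignment, Annotation, SequenceMatching, Coverage
RoxygenNote: 7.3.3
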