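Package: meiomapr
Title: Artifact-Aware Variant Refinement, Meiotic Recombination Detection,
    and Bulked-Segregant Causal Mapping
Version: 0.1.0
Authors@R: person("Maintainer", "Dev", email = "dev@example.org",
    role = c("aut", "cre"))
Description: A scriptable toolkit for obtaining high-confidence genetic
    markers from short-read resequencing data and applying them to meiotic
    analyses. Candidate SNPs and small indels are called from alignments (or
    imported from VCF), then refined by filtering artificial variants caused
    by structural variation (mis-mapped non-allelic reads at deletions,
    collapsed duplications), tandem repeats (reads that terminate inside a
    repeat), depth extremes, and aberrant allelic ratios. The surviving
    markers drive sliding-window genotyping of meiotic progeny to detect
    crossovers and gene conversions, and bulked-segregant analysis of pooled
    F2 populations to localize and annotate causal mutations (EMS transitions
    or T-DNA insertions). A simulator generates parental haplotypes,
    artifact-bearing alignments, recombinant progenies, and selected pools
    with full ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    methods,
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
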