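Package: founderCNV
Title: Recurrent Copy-Number Variant Detection, Haplotype Dating and
    Association in Founder Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing recurrent copy-number variants (rCNVs) in
    founder populations from SNP-array call sets. Implements dual-caller
    consensus filtering with probe, size and autosome retention rules;
    recurrent-CNV detection by shared breakpoints with cross-population
    matching; measurement of flanking shared haplotypes with a point-mutation
    rescue rule; coalescence (allele-age) estimation by the Gamma method on a
    genetic map, with chi-square pivot confidence intervals; carrier
    association statistics (odds ratios with Woolf intervals, chi-square
    tests, Bonferroni and Benjamini-Hochberg adjustment), per-person CNV
    burden with gene load, and power by simulation. A synthetic-data
    generator with known ground truth emulates haplotype decay around a
    focal CNV so that every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
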