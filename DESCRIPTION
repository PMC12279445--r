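Package: divscan
Title: Windowed Divergence and Selection Genome Scans for Multi-Population VCFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Missing-data-aware windowed population-genetic genome scans from VCF
    files that contain both variant and invariant sites. Implements count-based
    (ratio-of-sums) estimators of nucleotide diversity (Pi), absolute divergence
    (D_XY) and Hudson's F_ST with the Bhatia sample-size correction, windowed
    Tajima's D, standard-deviation-threshold classification of windows into four
    evolutionary scenarios (divergence with gene flow, allopatric selection,
    recurrent selection, balancing selection), a degenerate-site dN/dS statistic
    against an outgroup, and concordance of F_ST and dN/dS outliers to call genes
    under divergent selection. Includes a calibrated multi-population diploid
    genotype simulator with known ground truth (scenario and coding-gene
    injections) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
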