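Package: omicmatch
Title: Multi-Omics Sample Identity Verification by Genotype Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Verifies that multi-omics datasets (whole-genome sequencing,
    whole-genome bisulfite sequencing, RNA-seq and Illumina 450k methylation
    arrays) collected from the same cohort are correctly assigned to their
    donors. Genotypes are inferred from 450k SNP control-probe beta-values
    and from forced diploid likelihood calls on per-locus allele counts,
    with a bisulfite-aware mode that discards conversion-confounded
    observations at C/T and G/A polymorphisms. Pairwise genotype concordance
    matrices across modalities confirm sample identity and flag swaps.
    Includes a synthetic cohort generator with known ground truth
    (Hardy-Weinberg genotypes, tri-modal beta-value mixtures,
    Poisson-depth allele counts with bisulfite chemistry, expression-scaled
    RNA-seq coverage, injected label swaps) and the standard sequencing and
    array QC summary statistics (median coverage, fraction of bases at
    depth, duplication and GC percentages, detection p-value and bead-count
    pass rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
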