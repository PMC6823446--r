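# Small in-code fixtures shared across test files.

tiny_panel <- function() {
  locus_panel(c("rs1", "rs2", "rs3"), c("1", "1", "2"),
              c(100L, 200L, 300L), c("A", "C", "G"), c("G", "T", "A"))
}

tiny_manifest_df <- function() {
  data.frame(probe_id = c("p1", "p2", "p3"),
             id = c("rs1", "rs2", "rs3"),
             chrom = c("1", "1", "2"), pos = c(100L, 200L, 300L),
             ref = c("A", "C", "G"), alt = c("G", "T", "A"),
             high_beta_allele = c("alt", "ref", "alt"),
             stringsAsFactors = FALSE)
}

tiny_gm <- function(calls = rbind(s1 = c(0L, 1L, 2L),
                                  s2 = c(2L, NA, 0L)),
                    modality = "wgs") {
  colnames(calls) <- c("rs1", "rs2", "rs3")
  genotype_matrix(calls, tiny_panel(), modality)
}

# truth_set with a hand-picked panel, for chemistry-level count tests
manual_truth <- function(panel, calls, config) {
  structure(list(samples = rownames(calls), panel = panel, calls = calls,
                 genes = NULL, locus_gene = NULL, config = config),
            class = "truth_set")
}

# overall genotype accuracy of gm against the truth set, called cells only
call_accuracy <- function(gm, truth, loci = gm$panel$id) {
  ok <- gm$calls[, loci, drop = FALSE] ==
    truth$calls[rownames(gm$calls), loci, drop = FALSE]
  mean(ok, na.rm = TRUE)
}

# drop a beta matrix to blood columns relabelled by donor, for matching
blood_genotypes <- function(bm, ...) {
  array_donor_genotypes(bm, tissue = "blood", ...)
}
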