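# Small cohort with hand-placed loci and genes for gate-level checks:
# 10 samples, loci differing in carrier counts and gene expression rank.
selection_fixture <- function() {
  panel <- locus_panel(sprintf("l%d", 1:4), "2",
                       c(150L, 1150L, 2150L, 9999L),
                       rep("A", 4), rep("C", 4))
  calls <- matrix(0L, 10, 4,
                  dimnames = list(sprintf("s%02d", 1:10), panel$id))
  calls[1:4, "l1"] <- 1L       # variant in 4 samples, top gene
  calls[1:3, "l2"] <- 1L       # variant in only 3
  calls[1:5, "l3"] <- 2L       # variant in 5, low-ranked gene
  calls[1:6, "l4"] <- 1L       # variant in 6, no containing gene
  wgs <- genotype_matrix(calls, panel, "wgs")
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "2",
                      start = c(100L, 1100L, 2100L),
                      end = c(1000L, 2000L, 3000L))
  expr <- c(gA = 100, gB = 90, gC = 1)
  list(wgs = wgs, genes = genes, expr = expr)
}

test_that("both gates apply: carrier count and expression rank", {
  fx <- selection_fixture()
  sel <- select_rnaseq_loci(fx$wgs, fx$expr, fx$genes,
                            min_samples = 4, top_k = 2)
  # l1 passes both; l2 fails carriers; l3 fails rank; l4 maps to no gene
  expect_identical(sel$id, "l1")
  # widening the rank cut lets l3 in
  sel <- select_rnaseq_loci(fx$wgs, fx$expr, fx$genes,
                            min_samples = 4, top_k = 3)
  expect_identical(sel$id, c("l1", "l3"))
})

test_that("covered mode counts called samples instead of carriers", {
  fx <- selection_fixture()
  fx$wgs$calls["s05", "l2"] <- NA                   # 9 called, 3 carriers
  sel <- select_rnaseq_loci(fx$wgs, fx$expr, fx$genes, min_samples = 4,
                            top_k = 3, presence_mode = "covered")
  expect_true("l2" %in% sel$id)
  sel <- select_rnaseq_loci(fx$wgs, fx$expr, fx$genes, min_samples = 4,
                            top_k = 3, presence_mode = "variant")
  expect_false("l2" %in% sel$id)
})

test_that("selection is monotone in top_k and antitone in min_samples", {
  cfg <- sim_config(seed = 41)
  truth <- simulate_truth(cfg)
  wgs <- truth_genotype_matrix(truth, truth$exonic_panel)
  expr <- setNames(truth$genes$expression, truth$genes$gene_id)
  sizes_k <- vapply(c(25, 100, 500), function(k)
    nrow(select_rnaseq_loci(wgs, expr, truth$genes, top_k = k)),
    integer(1))
  expect_true(all(diff(sizes_k) >= 0))
  sizes_m <- vapply(c(2, 4, 8), function(m)
    nrow(select_rnaseq_loci(wgs, expr, truth$genes, min_samples = m)),
    integer(1))
  expect_true(all(diff(sizes_m) <= 0))
})

test_that("selection equals an independent two-filter re-implementation", {
  cfg <- sim_config(seed = 1)
  truth <- simulate_truth(cfg)
  wgs <- truth_genotype_matrix(truth, truth$exonic_panel)
  expr <- setNames(truth$genes$expression, truth$genes$gene_id)
  sel <- select_rnaseq_loci(wgs, expr, truth$genes,
                            min_samples = 4, top_k = 100)

  # oracle: brute-force row scans, filters applied in the other order
  ord <- order(-expr, names(expr))
  top <- names(expr)[ord][1:100]
  keep_rank <- vapply(seq_len(nrow(wgs$panel)), function(i) {
    g <- truth$genes
    hit <- which(g$chrom == wgs$panel$chrom[i] &
                   g$start <= wgs$panel$pos[i] & g$end >= wgs$panel$pos[i])
    length(hit) > 0 && g$gene_id[hit[1]] %in% top
  }, logical(1))
  keep_carrier <- vapply(seq_len(nrow(wgs$panel)), function(i)
    sum(wgs$calls[, i] >= 1, na.rm = TRUE) >= 4, logical(1))
  oracle_ids <- wgs$panel$id[keep_rank & keep_carrier]
  expect_setequal(sel$id, oracle_ids)
  expect_gt(nrow(sel), 0)

  # the two gates commute
  sel_rev <- select_rnaseq_loci(wgs, expr, truth$genes,
                                min_samples = 4, top_k = 100)
  expect_identical(sel$id, sel_rev$id)

  # output ordered by position and a subset of the candidates
  expect_false(is.unsorted(sel$pos[sel$chrom == "2"]))
  expect_true(all(sel$id %in% wgs$panel$id))
})

test_that("per-sample expression tables aggregate by the mean", {
  fx <- selection_fixture()
  tab <- data.frame(gene_id = names(fx$expr),
                    s1 = fx$expr * 2, s2 = fx$expr * 0)
  sel_tab <- select_rnaseq_loci(fx$wgs, tab, fx$genes,
                                min_samples = 4, top_k = 2)
  sel_vec <- select_rnaseq_loci(fx$wgs, fx$expr, fx$genes,
                                min_samples = 4, top_k = 2)
  expect_identical(sel_tab$id, sel_vec$id)
  expect_error(select_rnaseq_loci(fx$wgs, fx$expr, fx$genes,
                                  min_samples = 0), ">= 1")
})
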