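# Independent oracle: evaluate the three dosage likelihoods through
# dbinom and apply the het tie-break, without reusing the package's
# likelihood arithmetic.
oracle_dosage <- function(ref, alt, eps = 0.01) {
  p <- c(eps, 0.5, 1 - eps)
  ll <- dbinom(alt, ref + alt, p, log = TRUE)
  cand <- which(ll >= max(ll) - 1e-12) - 1L
  if (1L %in% cand) 1L else cand[1]
}

test_that("forced calls behave on canonical count patterns", {
  expect_identical(genotype_likelihoods(15, 0)$dosage, 0L)
  expect_identical(genotype_likelihoods(7, 8)$dosage, 1L)
  expect_identical(genotype_likelihoods(0, 20)$dosage, 2L)
  # depth gate: 1+2 < 4 -> no call, likelihoods still reported
  gl <- genotype_likelihoods(1, 2, min_depth = 4)
  expect_true(is.na(gl$dosage))
  expect_length(gl$loglik, 3L)
  # other-bucket reads count towards the gate only
  expect_false(is.na(genotype_likelihoods(1, 2, other_count = 1)$dosage))
  expect_error(genotype_likelihoods(5, 5, epsilon = 0), "epsilon")
  expect_error(genotype_likelihoods(5, 5, epsilon = 0.5), "epsilon")
})

test_that("likelihood argmax agrees with the binomial oracle, depth <= 50", {
  for (n in 1:50) for (alt in 0:n) {
    got <- genotype_likelihoods(n - alt, alt, min_depth = 1)$dosage
    expect_identical(got, oracle_dosage(n - alt, alt),
                     label = sprintf("ref=%d alt=%d", n - alt, alt))
  }
})

test_that("swapping ref and alt maps dosage d to 2 - d", {
  for (eps in c(0.005, 0.01, 0.05)) {
    for (n in c(4, 10, 30)) for (alt in 0:n) {
      d <- genotype_likelihoods(n - alt, alt, eps, min_depth = 1)$dosage
      ds <- genotype_likelihoods(alt, n - alt, eps, min_depth = 1)$dosage
      expect_identical(ds, 2L - d)
    }
  }
})

test_that("bisulfite count filtering drops exactly the confounded buckets", {
  # C/T site with reads on OT only: converted C mimics T, so T counts on
  # OT are discarded and only the C observations remain
  eff <- bisulfite_effective_counts(ref_ot = 6L, alt_ot = 9L,
                                    ref_ob = 0L, alt_ob = 0L,
                                    ref = "C", alt = "T")
  expect_identical(eff, list(ref = 6L, alt = 0L))
  # same site, OB reads are conversion-free and pass through
  eff <- bisulfite_effective_counts(6L, 9L, 5L, 4L, "C", "T")
  expect_identical(eff, list(ref = 11L, alt = 4L))
  # T as the reference allele: the T/OT bucket is the ref one
  eff <- bisulfite_effective_counts(6L, 9L, 5L, 4L, "T", "C")
  expect_identical(eff, list(ref = 5L, alt = 13L))
  # G/A site: confounded on OB instead
  eff <- bisulfite_effective_counts(6L, 9L, 5L, 4L, "G", "A")
  expect_identical(eff, list(ref = 11L, alt = 9L))
  # A/T site has no convertible allele: untouched
  eff <- bisulfite_effective_counts(6L, 9L, 5L, 4L, "A", "T")
  expect_identical(eff, list(ref = 11L, alt = 13L))
})

test_that("matrix building handles absent samples and foreign panels", {
  panel <- tiny_panel()
  df <- data.frame(sample_id = "s1", locus_id = "rs1",
                   ref_count_ot = 10L, alt_count_ot = 10L,
                   ref_count_ob = 0L, alt_count_ob = 0L, other_count = 0L)
  act <- allele_count_table(df, "wgs", panel)
  gm <- seq_genotype_matrix(act, panel)
  expect_identical(unname(gm$calls["s1", ]), c(1L, NA, NA))
  foreign <- locus_panel("rs9", "9", 1L, "A", "C")
  expect_error(seq_genotype_matrix(act, foreign), "rs9")
})

test_that("wgs caller recovers the truth at 30X with 1% error", {
  cfg <- sim_config(seed = 31)
  truth <- simulate_truth(cfg)
  act <- simulate_counts(truth, "wgs", cfg)
  gm <- seq_genotype_matrix(act, truth$panel)
  expect_gt(call_accuracy(gm, truth), 0.995)
})

test_that("recovery improves with depth and degrades with error rate", {
  acc <- function(depth, err, seed = 33) {
    cfg <- sim_config(n_individuals = 10L, n_array_loci = 40L,
                      n_exonic_loci = 5L, n_genes = 5L,
                      depth_mean = c(wgs = depth, wgbs = 15, rnaseq = 30),
                      base_error = err, seed = seed)
    truth <- simulate_truth(cfg)
    gm <- seq_genotype_matrix(simulate_counts(truth, "wgs", cfg),
                              truth$array_panel, epsilon = max(err, 0.01))
    call_accuracy(gm, truth, truth$array_panel$id)
  }
  expect_gte(acc(30, 0.05), acc(6, 0.05))
  expect_gte(acc(15, 0.01), acc(15, 0.10))
})

test_that("rnaseq loci in weakly expressed genes drop out as no-calls", {
  cfg <- sim_config(seed = 34)
  truth <- simulate_truth(cfg)
  act <- simulate_counts(truth, "rnaseq", cfg)
  gm <- seq_genotype_matrix(act, truth$exonic_panel)
  # (sample, locus) cells with no count row have zero depth: no-calls
  covered <- matrix(FALSE, nrow(gm$calls), ncol(gm$calls),
                    dimnames = dimnames(gm$calls))
  covered[cbind(act$counts$sample_id, act$counts$locus_id)] <- TRUE
  expect_gt(sum(!covered), 0)        # expression scaling creates dropout
  expect_true(all(is.na(gm$calls[!covered])))
  # dropout hits weakly expressed genes: call rate rises with expression
  expr <- truth$genes$expression[match(truth$locus_gene[gm$panel$id],
                                       truth$genes$gene_id)]
  lo <- expr <= median(expr)
  expect_gt(mean(covered[, !lo]), mean(covered[, lo]))
})
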