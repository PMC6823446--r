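test_that("config validation catches out-of-range parameters", {
  expect_error(sim_config(base_error = 1.2), "\\[0,1\\]")
  expect_error(sim_config(depth_mean = c(wgs = 0, wgbs = 15, rnaseq = 30)),
               "positive")
  expect_error(sim_config(beta_centers = c(0.5, 0.5, 0.9)), "increasing")
  expect_error(simulate_truth(sim_config(n_individuals = 1)),
               "at least 2")
})

test_that("degenerate Hardy-Weinberg: MAF 0 gives all-reference dosages", {
  truth <- simulate_truth(sim_config(array_maf = 0, n_exonic_loci = 5L,
                                     n_genes = 5L, seed = 3))
  expect_true(all(truth$calls[, truth$array_panel$id] == 0L))
})

test_that("HWE genotype frequencies recovered at large n (3-sigma CI)", {
  truth <- simulate_truth(sim_config(n_individuals = 10000L,
                                     n_array_loci = 1L,
                                     n_exonic_loci = 2L, n_genes = 2L,
                                     seed = 11))
  g <- truth$calls[, truth$array_panel$id[1]]
  n <- length(g)
  for (d in 0:2) {
    p <- c(0.25, 0.5, 0.25)[d + 1]
    expect_lt(abs(sum(g == d) - n * p), 3 * sqrt(n * p * (1 - p)))
  }
})

test_that("identical seeds reproduce every dataset exactly", {
  cfg <- sim_config(n_individuals = 4L, n_array_loci = 10L,
                    n_exonic_loci = 20L, n_genes = 10L, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth$calls, b$truth$calls)
  expect_identical(a$truth$genes, b$truth$genes)
  expect_identical(a$beta$beta, b$beta$beta)
  expect_identical(a$beta$detection_p, b$beta$detection_p)
  for (pr in c("wgs", "wgbs", "rnaseq"))
    expect_identical(a[[pr]]$counts, b[[pr]]$counts)
})

test_that("zero noise collapses beta-values onto the class centres", {
  cfg <- sim_config(n_individuals = 3L, n_array_loci = 20L,
                    n_exonic_loci = 5L, n_genes = 5L,
                    beta_noise_sd = 0, seed = 5)
  truth <- simulate_truth(cfg)
  bm <- simulate_array(truth, cfg)
  expect_true(all(bm$beta %in% cfg$beta_centers))
})

test_that("observed depth matches the Poisson mean within 3 sigma", {
  cfg <- sim_config(n_individuals = 10L, n_array_loci = 50L,
                    n_exonic_loci = 50L, n_genes = 20L, seed = 9)
  truth <- simulate_truth(cfg)
  act <- simulate_counts(truth, "wgs", cfg)
  # total depth over N cells ~ Poisson(N * 30); zero-depth cells are absent
  n_cells <- length(truth$samples) * nrow(truth$panel)
  total <- sum(count_depth(act))
  lambda <- n_cells * cfg$depth_mean[["wgs"]]
  expect_lt(abs(total - lambda), 3 * sqrt(lambda))
})

test_that("full conversion with no methylation wipes C reads on OT", {
  # C/T SNP: with methylation_rate 0 and conversion_rate 1 every
  # original-top read reports T whatever the genotype — the confound the
  # bisulfite-aware caller must survive
  cfg <- sim_config(n_individuals = 2L, base_error = 0,
                    methylation_rate = 0, conversion_rate = 1, seed = 2)
  panel <- locus_panel("ct1", "1", 100L, "C", "T")
  calls <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("i1", "i2"), "ct1"))
  truth <- manual_truth(panel, calls, cfg)
  act <- simulate_counts(truth, "wgbs", cfg)
  expect_true(all(act$counts$ref_count_ot == 0L))   # no OT read stays C
  ot_reads <- act$counts$alt_count_ot
  expect_true(any(ot_reads > 0))                    # they all report T
})

test_that("dosage 0 with no errors yields zero alt counts", {
  cfg <- sim_config(n_individuals = 2L, base_error = 0, seed = 8)
  panel <- locus_panel(c("l1", "l2"), c("1", "1"), c(10L, 20L),
                       c("A", "G"), c("C", "A"))
  calls <- matrix(0L, 2, 2, dimnames = list(c("i1", "i2"), panel$id))
  truth <- manual_truth(panel, calls, cfg)
  act <- simulate_counts(truth, "wgs", cfg)
  expect_true(all(act$counts$alt_count_ot + act$counts$alt_count_ob == 0L))
  expect_true(all(act$counts$other_count == 0L))
})

test_that("rnaseq simulation requires a gene table", {
  cfg <- sim_config(seed = 2)
  panel <- locus_panel("l1", "1", 10L, "A", "C")
  calls <- matrix(1L, 2, 1, dimnames = list(c("i1", "i2"), "l1"))
  truth <- manual_truth(panel, calls, cfg)
  truth$exonic_panel <- panel
  expect_error(simulate_counts(truth, "rnaseq", cfg), "gene table")
})

test_that("inject_swap relabels observations and validates bijections", {
  cfg <- sim_config(n_individuals = 4L, n_array_loci = 8L,
                    n_exonic_loci = 5L, n_genes = 5L, seed = 6)
  co <- simulate_cohort(cfg)
  ids <- co$truth$samples

  identity_perm <- setNames(ids, ids)
  expect_identical(inject_swap(co$wgs, identity_perm)$counts,
                   co$wgs$counts)
  expect_identical(inject_swap(co$beta, identity_perm)$beta, co$beta$beta)

  tr <- setNames(c(ids[2], ids[1]), c(ids[1], ids[2]))
  sw <- inject_swap(co$wgs, tr)
  orig1 <- co$wgs$counts[co$wgs$counts$sample_id == ids[1], -1]
  now2 <- sw$counts[sw$counts$sample_id == ids[2], -1]
  expect_identical(orig1, now2)   # ind1's counts now carry ind2's label

  expect_error(inject_swap(co$wgs, setNames(c(ids[2], ids[2]), ids[1:2])),
               "bijection")
})

test_that("write_simulation emits a reloadable plain-text bundle", {
  cfg <- sim_config(n_individuals = 3L, n_array_loci = 6L,
                    n_exonic_loci = 5L, n_genes = 5L, seed = 13)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_simulation(co, dir)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_identical(as.data.frame(man), as.data.frame(co$truth$array_manifest))
  tv <- read_genotype_vcf(file.path(dir, "truth.vcf"))
  expect_identical(tv$calls, co$truth$calls)
  act <- read_allele_counts(file.path(dir, "wgs_counts.tsv"), "wgs",
                            co$truth$panel)
  expect_identical(act$counts, co$wgs$counts)
  expect_true(file.exists(file.path(dir, "run_manifest.txt")))
})
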