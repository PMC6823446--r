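#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator. Defaults
#' describe a ten-donor multi-omics study: a 65-probe array SNP panel with
#' maximally informative loci (MAF 0.5), ~300 exonic loci spread over 500
#' genes, WGS at 30X and WGBS at 15X mean depth, RNA-seq depth scaled by
#' gene expression, 1% per-read base error, 99.5% bisulfite conversion and
#' 75% CpG methylation, tri-modal beta-values centred at 0.05/0.50/0.95
#' with sd 0.04, a 5e-4 detection-p failure rate and mean bead count 14.
#'
#' @param n_individuals number of donors (>= 2).
#' @param n_array_loci size of the array SNP control-probe panel.
#' @param n_exonic_loci number of candidate exonic loci.
#' @param n_genes number of genes carrying the exonic loci.
#' @param array_maf minor-allele frequency of array panel loci (scalar).
#' @param exonic_maf_range range from which per-locus exonic MAFs are drawn
#'   uniformly.
#' @param depth_mean named vector of mean sequencing depths per protocol.
#' @param base_error per-read probability of reporting a wrong base.
#' @param conversion_rate bisulfite conversion efficiency (unmethylated C
#'   read as T).
#' @param methylation_rate per-read probability that a cytosine is
#'   methylated (and therefore protected from conversion).
#' @param beta_centers beta-value peak centres for dosage classes
#'   LOW/MID/HIGH; strictly increasing, inside \[0,1\].
#' @param beta_noise_sd Gaussian beta noise sd (values censored to \[0,1\]).
#' @param detp_fail_rate probability a probe fails detection (p >= 0.01).
#' @param bead_mean Poisson mean of per-probe bead counts.
#' @param allelic_imbalance_sd sd of the per-(sample,locus) log-odds shift
#'   of the alt-allele fraction at heterozygous RNA-seq loci.
#' @param expression_sdlog log-normal sdlog of gene expression levels.
#' @param seed integer master seed; per-stage substreams are derived from
#'   it by hashing the stage name, so adding a stage never perturbs
#'   earlier ones.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_individuals = 10L,
                       n_array_loci = 65L,
                       n_exonic_loci = 300L,
                       n_genes = 500L,
                       array_maf = 0.5,
                       exonic_maf_range = c(0.05, 0.5),
                       depth_mean = c(wgs = 30, wgbs = 15, rnaseq = 30),
                       base_error = 0.01,
                       conversion_rate = 0.995,
                       methylation_rate = 0.75,
                       beta_centers = c(0.05, 0.50, 0.95),
                       beta_noise_sd = 0.04,
                       detp_fail_rate = 5e-4,
                       bead_mean = 14,
                       allelic_imbalance_sd = 0.5,
                       expression_sdlog = 1.5,
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_array_loci = as.integer(n_array_loci),
              n_exonic_loci = as.integer(n_exonic_loci),
              n_genes = as.integer(n_genes),
              array_maf = array_maf, exonic_maf_range = exonic_maf_range,
              depth_mean = depth_mean, base_error = base_error,
              conversion_rate = conversion_rate,
              methylation_rate = methylation_rate,
              beta_centers = beta_centers, beta_noise_sd = beta_noise_sd,
              detp_fail_rate = detp_fail_rate, bead_mean = bead_mean,
              allelic_imbalance_sd = allelic_imbalance_sd,
              expression_sdlog = expression_sdlog, seed = as.integer(seed))
  probs <- c(cfg$base_error, cfg$conversion_rate, cfg$methylation_rate,
             cfg$detp_fail_rate, cfg$array_maf, cfg$exonic_maf_range)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0,1]")
  if (any(cfg$depth_mean <= 0)) stop("depth means must be positive")
  if (!all(c("wgs", "wgbs", "rnaseq") %in% names(cfg$depth_mean)))
    stop("depth_mean needs entries wgs, wgbs and rnaseq")
  if (length(cfg$beta_centers) != 3 || any(diff(cfg$beta_centers) <= 0))
    stop("beta_centers must be three strictly increasing values")
  if (any(cfg$beta_centers < 0) || any(cfg$beta_centers > 1))
    stop("beta_centers must lie in [0,1]")
  if (cfg$beta_noise_sd < 0 || cfg$allelic_imbalance_sd < 0)
    stop("noise sds must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

# Stable per-stage substream seed: djb2-style hash of the stage name folded
# with the master seed, kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- 5381
  for (code in utf8ToInt(stage)) h <- (h * 33 + code) %% 2147483647
  as.integer((h + as.numeric(seed) * 48271) %% 2147483647)
}

# Run expr under a temporary RNG state seeded for the given stage,
# restoring the caller's state afterwards.
with_stage_rng <- function(seed, stage, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}

BASES <- c("A", "C", "G", "T")

#' Simulate ground-truth genotypes, genes and expression
#'
#' Draws per-locus Hardy-Weinberg genotypes for a synthetic cohort over an
#' array SNP panel plus a set of exonic loci, each exonic locus belonging
#' to exactly one gene with a log-normal expression level.
#'
#' @param config a [sim_config()].
#' @return A `truth_set` list: `samples`; `panel` (array + exonic loci);
#'   `calls` (truth dosage matrix, samples x loci); `array_manifest`;
#'   `array_panel`; `exonic_panel`; `genes` (gene_id, chrom, start, end,
#'   expression); `locus_gene` (locus id -> gene id for exonic loci);
#'   `maf` (per locus); `config`.
#' @export
simulate_truth <- function(config) {
  if (config$n_individuals < 2)
    stop("matching needs at least 2 individuals")
  with_stage_rng(config$seed, "truth", {
    samples <- sprintf("ind%02d", seq_len(config$n_individuals))

    ## array panel: SNP control probes, deliberately common variants
    na <- config$n_array_loci
    a_ref <- sample(BASES, na, replace = TRUE)
    a_alt <- vapply(a_ref, function(r) sample(setdiff(BASES, r), 1),
                    character(1))
    array_manifest <- as_manifest(data.frame(
      probe_id = sprintf("rsprobe%03d", seq_len(na)),
      id = sprintf("arr_rs%03d", seq_len(na)),
      chrom = "1", pos = 100000L * seq_len(na),
      ref = a_ref, alt = unname(a_alt),
      high_beta_allele = sample(c("ref", "alt"), na, replace = TRUE),
      stringsAsFactors = FALSE))
    array_panel <- manifest_panel(array_manifest, name = "array")

    ## genes: non-overlapping intervals on chromosome 2, log-normal expression
    ng <- config$n_genes
    genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(ng)),
                        chrom = "2",
                        start = 10000L * (seq_len(ng) - 1L) + 1L,
                        end = 10000L * (seq_len(ng) - 1L) + 5000L,
                        expression = rlnorm(ng, meanlog = 3,
                                            sdlog = config$expression_sdlog),
                        stringsAsFactors = FALSE)

    ## exonic loci: each inside one gene
    ne <- config$n_exonic_loci
    gene_idx <- sort(sample.int(ng, ne, replace = TRUE))
    within <- stats::ave(seq_len(ne), gene_idx, FUN = seq_along)
    e_ref <- sample(BASES, ne, replace = TRUE)
    e_alt <- vapply(e_ref, function(r) sample(setdiff(BASES, r), 1),
                    character(1))
    exonic_panel <- locus_panel(
      id = sprintf("exo_rs%04d", seq_len(ne)),
      chrom = "2", pos = genes$start[gene_idx] + 10L * within,
      ref = e_ref, alt = unname(e_alt), name = "exonic")
    locus_gene <- setNames(genes$gene_id[gene_idx], exonic_panel$id)

    panel <- locus_panel(c(array_panel$id, exonic_panel$id),
                         c(array_panel$chrom, exonic_panel$chrom),
                         c(array_panel$pos, exonic_panel$pos),
                         c(array_panel$ref, exonic_panel$ref),
                         c(array_panel$alt, exonic_panel$alt),
                         name = "truth")
    maf <- setNames(c(rep(config$array_maf, na),
                      runif(ne, config$exonic_maf_range[1],
                            config$exonic_maf_range[2])), panel$id)

    ## Hardy-Weinberg: dosage ~ Binomial(2, maf) per individual
    calls <- matrix(rbinom(length(samples) * nrow(panel), 2L,
                           rep(maf, each = length(samples))),
                    nrow = length(samples), ncol = nrow(panel),
                    dimnames = list(samples, panel$id))
    storage.mode(calls) <- "integer"

    structure(list(samples = samples, panel = panel, calls = calls,
                   array_manifest = array_manifest,
                   array_panel = array_panel, exonic_panel = exonic_panel,
                   genes = genes, locus_gene = locus_gene, maf = maf,
                   config = config),
              class = "truth_set")
  })
}

#' Truth genotypes as a genotype_matrix over a panel
#'
#' @param truth a `truth_set`.
#' @param panel a [locus_panel()] whose loci are a subset of the truth
#'   panel (default: the full truth panel).
#' @param modality modality tag for the result.
#' @return A [genotype_matrix()] of the true dosages.
#' @export
truth_genotype_matrix <- function(truth, panel = truth$panel,
                                  modality = "wgs") {
  miss <- setdiff(panel$id, colnames(truth$calls))
  if (length(miss)) stop("locus not in truth set: ", miss[1])
  genotype_matrix(truth$calls[, panel$id, drop = FALSE], panel, modality)
}

#' Simulate a 450k SNP control-probe run for blood and saliva
#'
#' Each donor contributes two tissue columns that share the donor's true
#' genotype. Beta-values are drawn around the class centre given by the
#' dosage (oriented by each probe's `high_beta_allele`) with Gaussian
#' noise censored to \[0,1\] and rounded to 6 decimals; detection
#' p-values are small except for rare failures, and bead counts are
#' Poisson.
#'
#' @param truth a `truth_set`.
#' @param config a [sim_config()] (defaults to the truth set's).
#' @return A [beta_matrix()] with columns `<donor>_blood`, `<donor>_saliva`.
#' @export
simulate_array <- function(truth, config = truth$config) {
  with_stage_rng(config$seed, "array", {
    man <- truth$array_manifest
    dos <- t(truth$calls[, man$id, drop = FALSE])      # probes x donors
    # class index 1/2/3 = LOW/MID/HIGH after allele orientation
    alt_high <- man$high_beta_allele == "alt"
    cls <- dos + 1L
    cls[!alt_high, ] <- 3L - dos[!alt_high, , drop = FALSE]
    cols <- paste0(rep(truth$samples, each = 2), c("_blood", "_saliva"))
    cls2 <- cls[, rep(seq_along(truth$samples), each = 2), drop = FALSE]
    dimnames(cls2) <- list(man$probe_id, cols)
    centers <- config$beta_centers
    beta <- centers[cls2] + rnorm(length(cls2), 0, config$beta_noise_sd)
    beta <- round(pmin(1, pmax(0, beta)), 6)
    beta <- matrix(beta, nrow = nrow(cls2), dimnames = dimnames(cls2))
    fail <- matrix(runif(length(cls2)) < config$detp_fail_rate,
                   nrow = nrow(cls2))
    detp <- matrix(runif(length(cls2), 0, 0.001), nrow = nrow(cls2),
                   dimnames = dimnames(cls2))
    detp[fail] <- runif(sum(fail), 0.01, 1)
    detp <- round(detp, 6)
    beads <- matrix(rpois(length(cls2), config$bead_mean),
                    nrow = nrow(cls2), dimnames = dimnames(cls2))
    beta_matrix(beta, detp, beads, man)
  })
}

#' Simulate strand-resolved allele counts for a sequencing protocol
#'
#' Per (sample, locus) the read depth is Poisson: at the protocol's mean
#' for WGS/WGBS, and scaled by the locus's gene expression (normalised so
#' the panel mean equals the configured mean) for RNA-seq, which makes
#' loci in weakly expressed genes drop out. Each read carries the true
#' allele (alt with probability dosage/2, shifted by a log-normal allelic
#' imbalance at RNA-seq heterozygotes) and is misread as a uniformly
#' chosen other base with probability `base_error`. WGBS reads are
#' assigned a template strand (OT/OB) fairly; an unmethylated cytosine on
#' the read's strand is bisulfite-converted with probability
#' `conversion_rate`, so C reads become T on OT and G reads become A on
#' OB — the confound [bisulfite_effective_counts()] must survive.
#'
#' @param truth a `truth_set`.
#' @param protocol `"wgs"`, `"wgbs"` or `"rnaseq"`.
#' @param config a [sim_config()] (defaults to the truth set's).
#' @return An [allele_count_table()]; (sample, locus) pairs with zero
#'   depth are absent. WGS/WGBS cover the full truth panel, RNA-seq the
#'   exonic panel only.
#' @export
simulate_counts <- function(truth, protocol, config = truth$config) {
  protocol <- match.arg(protocol, c("wgs", "wgbs", "rnaseq"))
  panel <- if (protocol == "rnaseq") truth$exonic_panel else truth$panel
  if (protocol == "rnaseq" && is.null(truth$genes))
    stop("rnaseq simulation requires a gene table")
  with_stage_rng(config$seed, paste0("counts_", protocol), {
    mu <- rep(config$depth_mean[[protocol]], nrow(panel))
    if (protocol == "rnaseq") {
      expr <- truth$genes$expression[match(truth$locus_gene[panel$id],
                                           truth$genes$gene_id)]
      mu <- mu * expr / mean(expr)
    }
    eps <- config$base_error
    rows <- vector("list", length(truth$samples) * nrow(panel))
    k <- 0L
    for (s in truth$samples) {
      for (i in seq_len(nrow(panel))) {
        n <- rpois(1, mu[i])
        if (n == 0) next
        d <- truth$calls[s, panel$id[i]]
        p_alt <- d / 2
        if (protocol == "rnaseq" && d == 1L)
          p_alt <- stats::plogis(rnorm(1, 0, config$allelic_imbalance_sd))
        base <- ifelse(runif(n) < p_alt, panel$alt[i], panel$ref[i])
        err <- runif(n) < eps
        if (any(err)) {
          pick <- ceiling(runif(sum(err)) * 3)   # offset among the 3 others
          base[err] <- vapply(seq_len(sum(err)), function(j)
            setdiff(BASES, base[err][j])[pick[j]], character(1))
        }
        if (protocol == "wgbs") {
          ot <- runif(n) < 0.5
          meth <- runif(n) < config$methylation_rate
          conv <- runif(n) < config$conversion_rate
          flip <- !meth & conv
          base[ot & flip & base == "C"] <- "T"
          base[!ot & flip & base == "G"] <- "A"
        } else {
          ot <- rep(TRUE, n)
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample_id = s, locus_id = panel$id[i],
          ref_count_ot = sum(ot & base == panel$ref[i]),
          alt_count_ot = sum(ot & base == panel$alt[i]),
          ref_count_ob = sum(!ot & base == panel$ref[i]),
          alt_count_ob = sum(!ot & base == panel$alt[i]),
          other_count = sum(base != panel$ref[i] & base != panel$alt[i]),
          stringsAsFactors = FALSE)
      }
    }
    allele_count_table(do.call(rbind, rows[seq_len(k)]), protocol, panel)
  })
}

#' Relabel samples according to a permutation (a simulated swap)
#'
#' Reassigns observation data to new sample labels while leaving values
#' untouched — exactly what an upstream labelling mistake does. The truth
#' set is never relabelled, so downstream identity checks can be scored
#' against it.
#'
#' @param x a [beta_matrix()], [allele_count_table()] or
#'   [genotype_matrix()].
#' @param permutation named character vector mapping old donor ids to new
#'   ones; must be a bijection. Donors absent from it keep their label.
#' @return An object of the same class with relabelled samples.
#' @export
inject_swap <- function(x, permutation) {
  if (anyDuplicated(names(permutation)) || anyDuplicated(permutation) ||
      !setequal(names(permutation), permutation))
    stop("permutation is not a bijection over its sample ids")
  UseMethod("inject_swap")
}

relabel <- function(ids, permutation) {
  hit <- ids %in% names(permutation)
  ids[hit] <- unname(permutation[ids[hit]])
  ids
}

#' @export
inject_swap.genotype_matrix <- function(x, permutation) {
  rownames(x$calls) <- relabel(rownames(x$calls), permutation)
  x
}

#' @export
inject_swap.allele_count_table <- function(x, permutation) {
  x$counts$sample_id <- relabel(x$counts$sample_id, permutation)
  x
}

#' @export
inject_swap.beta_matrix <- function(x, permutation) {
  info <- beta_samples(x)
  newcols <- paste(relabel(info$donor, permutation), info$tissue, sep = "_")
  for (f in c("beta", "detection_p", "bead_count")) colnames(x[[f]]) <- newcols
  x
}

#' Simulate a full multi-omics cohort
#'
#' Convenience wrapper: truth, array beta matrix and allele counts for all
#' three sequencing protocols, optionally with a label swap applied to
#' every observation dataset.
#'
#' @param config a [sim_config()].
#' @param swap optional permutation passed to [inject_swap()].
#' @return list with `truth`, `beta`, `wgs`, `wgbs`, `rnaseq`, `swap`.
#' @export
simulate_cohort <- function(config = sim_config(), swap = NULL) {
  truth <- simulate_truth(config)
  out <- list(truth = truth,
              beta = simulate_array(truth, config),
              wgs = simulate_counts(truth, "wgs", config),
              wgbs = simulate_counts(truth, "wgbs", config),
              rnaseq = simulate_counts(truth, "rnaseq", config),
              swap = swap)
  if (!is.null(swap))
    for (f in c("beta", "wgs", "wgbs", "rnaseq"))
      out[[f]] <- inject_swap(out[[f]], swap)
  out
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the manifest TSV, truth VCF, beta/detection-p/bead-count TSVs,
#' per-protocol allele-count TSVs, gene BED + expression TSV and a
#' key-value run manifest echoing the seed and configuration.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_manifest(cohort$truth$array_manifest, fp("manifest.tsv"))
  write_genotype_vcf(truth_genotype_matrix(cohort$truth), fp("truth.vcf"))
  write_beta_matrix(cohort$beta, fp("beta.tsv"), fp("detection_p.tsv"),
                    fp("bead_count.tsv"))
  for (pr in c("wgs", "wgbs", "rnaseq"))
    write_allele_counts(cohort[[pr]], fp(paste0(pr, "_counts.tsv")))
  write_gene_bed(cohort$truth$genes, fp("genes.bed"))
  write.table(cohort$truth$genes[c("gene_id", "expression")],
              fp("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- cohort$truth$config
  flat <- vapply(names(cfg), function(nm)
    paste0(nm, ": ", paste(format(cfg[[nm]], digits = 10), collapse = ",")),
    character(1))
  writeLines(c(flat, if (!is.null(cohort$swap))
    paste0("swap: ", paste(names(cohort$swap), cohort$swap, sep = ">",
                           collapse = ","))), fp("run_manifest.txt"))
  invisible(dir)
}
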