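#' Diploid genotype likelihoods from allele counts
#'
#' Forced call at a known biallelic site: under dosage d the probability
#' that a read shows the alt allele is p_d = (d/2)(1-eps) + (1-d/2)eps,
#' so the log-likelihood of (ref_count, alt_count) is
#' `alt*log(p_d) + ref*log(1-p_d)`. With a flat prior the call is the
#' maximising dosage; exact ties break towards the heterozygote (dosage
#' 1), whose mismatches are symmetric in downstream concordance. Reads in
#' the `other` bucket count towards the depth gate but not the
#' likelihood.
#'
#' @param ref_count,alt_count non-negative read counts.
#' @param epsilon per-read error rate, in (0, 0.5).
#' @param min_depth minimum total depth to emit a call (default 4).
#' @param other_count reads supporting neither allele (depth gate only).
#' @return list: `loglik` (named vector for dosages 0/1/2), `dosage`
#'   (integer or `NA` when gated), `depth`.
#' @examples
#' genotype_likelihoods(15, 0)$dosage   # 0
#' genotype_likelihoods(7, 8)$dosage    # 1
#' @export
genotype_likelihoods <- function(ref_count, alt_count, epsilon = 0.01,
                                 min_depth = 4L, other_count = 0L) {
  if (epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie strictly inside (0, 0.5)")
  if (ref_count < 0 || alt_count < 0 || other_count < 0)
    stop("counts must be non-negative")
  p <- c(epsilon, 0.5, 1 - epsilon)
  ll <- alt_count * log(p) + ref_count * log(1 - p)
  names(ll) <- c("0", "1", "2")
  depth <- ref_count + alt_count + other_count
  dosage <- if (depth < min_depth) NA_integer_ else map_dosage(ll)
  list(loglik = ll, dosage = dosage, depth = depth)
}

# argmax over dosages with ties broken towards the heterozygote
map_dosage <- function(ll) {
  best <- max(ll)
  cand <- unname(which(ll >= best - 1e-12)) - 1L
  if (1L %in% cand) 1L else cand[1]
}

#' Conversion-safe allele counts for bisulfite data
#'
#' Bisulfite chemistry reads unmethylated C as T, strand-specifically: a
#' genomic C/T polymorphism is confounded on the original-top (OT) strand
#' (a converted C is indistinguishable from the T allele) and a G/A
#' polymorphism on the original-bottom (OB) strand. Observations that
#' conversion could have manufactured are discarded: for a C/T site the
#' T-allele counts on OT are dropped (OT C observations are safe — only a
#' genuine, methylated C can produce them — and the OB G/A reads are
#' untouched); symmetrically for G/A sites. All other allele pairs pass
#' through unchanged.
#'
#' @param ref_ot,alt_ot,ref_ob,alt_ob strand-resolved counts.
#' @param ref,alt the site's alleles.
#' @return list `ref`, `alt`: effective counts for [genotype_likelihoods()].
#' @export
bisulfite_effective_counts <- function(ref_ot, alt_ot, ref_ob, alt_ob,
                                       ref, alt) {
  pair <- paste0(ref, alt)
  if (pair %in% c("CT", "TC")) {
    # drop the T allele's OT bucket
    if (ref == "T") ref_ot <- 0L else alt_ot <- 0L
  } else if (pair %in% c("GA", "AG")) {
    # drop the A allele's OB bucket
    if (ref == "A") ref_ob <- 0L else alt_ob <- 0L
  }
  list(ref = ref_ot + ref_ob, alt = alt_ot + alt_ob)
}

#' Forced genotype calls over a panel from an allele count table
#'
#' One call per (sample, panel locus). Pairs without rows in the table
#' have zero coverage and are no-calls, as are pairs below `min_depth`.
#' For WGBS tables the conversion-confounded observations are removed by
#' [bisulfite_effective_counts()] before the likelihood is evaluated
#' (disable with `bisulfite_aware = FALSE` to get the naive caller).
#'
#' @param act an [allele_count_table()].
#' @param panel a [locus_panel()]; must be covered by the table's panel.
#' @param epsilon,min_depth passed to [genotype_likelihoods()].
#' @param bisulfite_aware apply the conversion filter (default: protocol
#'   is `"wgbs"`).
#' @return A [genotype_matrix()] tagged with the table's protocol.
#' @export
seq_genotype_matrix <- function(act, panel = act$panel, epsilon = 0.01,
                                min_depth = 4L,
                                bisulfite_aware = act$protocol == "wgbs") {
  miss <- setdiff(panel$id, act$panel$id)
  if (length(miss)) stop("panel locus absent from count table's panel: ",
                         miss[1])
  df <- act$counts
  samples <- sort(unique(df$sample_id))
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(panel),
                  dimnames = list(samples, panel$id))
  keep <- df$locus_id %in% panel$id
  df <- df[keep, , drop = FALSE]
  ref <- setNames(panel$ref, panel$id)
  alt <- setNames(panel$alt, panel$id)
  for (r in seq_len(nrow(df))) {
    lid <- df$locus_id[r]
    if (bisulfite_aware) {
      eff <- bisulfite_effective_counts(df$ref_count_ot[r], df$alt_count_ot[r],
                                        df$ref_count_ob[r], df$alt_count_ob[r],
                                        ref[[lid]], alt[[lid]])
    } else {
      eff <- list(ref = df$ref_count_ot[r] + df$ref_count_ob[r],
                  alt = df$alt_count_ot[r] + df$alt_count_ob[r])
    }
    gl <- genotype_likelihoods(eff$ref, eff$alt, epsilon, min_depth,
                               other_count = df$other_count[r])
    calls[df$sample_id[r], lid] <- gl$dosage
  }
  genotype_matrix(calls, panel, act$protocol)
}
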