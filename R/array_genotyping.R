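#' Classify a beta-value into a zygosity class
#'
#' At SNP control probes the beta-value distribution is tri-modal: a peak
#' near 0.5 for heterozygotes and peaks near 0 and 1 for the two
#' homozygotes. Classification is by fixed cuts — the peaks are far apart
#' by array design, so no mixture fit is needed.
#'
#' @param beta numeric vector in \[0,1\]; `NA` allowed.
#' @param low_cut,high_cut class boundaries, `0 <= low_cut < high_cut <= 1`
#'   (defaults 0.25 / 0.75). Values strictly below `low_cut` are `LOW`,
#'   strictly above `high_cut` are `HIGH`, everything else (cuts included)
#'   is `MID`.
#' @return character vector over `{"LOW","MID","HIGH","NO_CALL"}`; `NA`
#'   input gives `NO_CALL`.
#' @examples
#' classify_beta(c(0.02, 0.5, 0.97, NA))
#' @export
classify_beta <- function(beta, low_cut = 0.25, high_cut = 0.75) {
  if (!(low_cut >= 0 && low_cut < high_cut && high_cut <= 1))
    stop("need 0 <= low_cut < high_cut <= 1")
  b <- beta[!is.na(beta)]
  if (length(b) && (any(b < 0) || any(b > 1)))
    stop("beta-values outside [0,1]")
  out <- rep("MID", length(beta))
  out[beta < low_cut] <- "LOW"
  out[beta > high_cut] <- "HIGH"
  out[is.na(beta)] <- "NO_CALL"
  out
}

#' Genotype calls from SNP control-probe beta-values
#'
#' Maps each probe's zygosity class to an alt-allele dosage using the
#' manifest's `high_beta_allele` orientation: `MID` is always dosage 1;
#' `HIGH` is 2 when the alt allele drives beta towards 1, else 0; `LOW` is
#' the complement. With `qc_filter`, cells failing detection
#' (p >= `p_cut`) or measured by fewer than `bead_cut` beads become
#' no-calls.
#'
#' @param bm a [beta_matrix()].
#' @param qc_filter apply the detection-p / bead-count filter (default
#'   off).
#' @param low_cut,high_cut passed to [classify_beta()].
#' @param p_cut,bead_cut QC thresholds (defaults 0.01 and 3).
#' @return A [genotype_matrix()] with modality `"array"`, one row per
#'   sample column of `bm`.
#' @export
array_genotypes <- function(bm, qc_filter = FALSE, low_cut = 0.25,
                            high_cut = 0.75, p_cut = 0.01, bead_cut = 3) {
  man <- bm$manifest
  cls <- matrix(classify_beta(bm$beta, low_cut, high_cut),
                nrow = nrow(bm$beta), dimnames = dimnames(bm$beta))
  if (qc_filter) {
    bad <- (!is.na(bm$detection_p) & bm$detection_p >= p_cut) |
      (!is.na(bm$bead_count) & bm$bead_count < bead_cut) |
      is.na(bm$detection_p) | is.na(bm$bead_count)
    cls[bad] <- "NO_CALL"
  }
  alt_high <- man$high_beta_allele == "alt"
  dos <- matrix(NA_integer_, nrow = nrow(cls), ncol = ncol(cls),
                dimnames = dimnames(cls))
  dos[cls == "MID"] <- 1L
  high <- cls == "HIGH"; low <- cls == "LOW"
  dos[high & alt_high] <- 2L
  dos[high & !alt_high] <- 0L
  dos[low & alt_high] <- 0L
  dos[low & !alt_high] <- 2L
  panel <- manifest_panel(man)
  calls <- t(dos)
  colnames(calls) <- panel$id
  genotype_matrix(calls, panel, "array")
}

#' Blood-vs-saliva zygosity consistency check
#'
#' Both tissues of a donor carry the same germline genotype, so their
#' SNP control-probe zygosity classes must agree; disagreement indicates
#' a sample handling problem. Agreement is computed on the class level
#' over probes called in both tissues.
#'
#' @param bm a [beta_matrix()] with `<donor>_blood` and `<donor>_saliva`
#'   columns.
#' @param tissues the two tissue labels to compare.
#' @param low_cut,high_cut passed to [classify_beta()].
#' @return data.frame with one row per donor: `donor`, `n_shared`,
#'   `n_match`, `agreement_pct` (`NA` when unevaluable), `status`
#'   (`"evaluated"` or `"unevaluable"`), `mismatch_probes`
#'   (comma-separated ids, `""` when none).
#' @export
cross_tissue_check <- function(bm, tissues = c("blood", "saliva"),
                               low_cut = 0.25, high_cut = 0.75) {
  info <- beta_samples(bm)
  donors <- unique(info$donor)
  cls <- matrix(classify_beta(bm$beta, low_cut, high_cut),
                nrow = nrow(bm$beta), dimnames = dimnames(bm$beta))
  out <- lapply(donors, function(d) {
    c1 <- paste(d, tissues[1], sep = "_")
    c2 <- paste(d, tissues[2], sep = "_")
    if (!(c1 %in% info$column) || !(c2 %in% info$column))
      return(data.frame(donor = d, n_shared = 0L, n_match = 0L,
                        agreement_pct = NA_real_, status = "unevaluable",
                        mismatch_probes = "", stringsAsFactors = FALSE))
    a <- cls[, c1]; b <- cls[, c2]
    both <- a != "NO_CALL" & b != "NO_CALL"
    n_shared <- sum(both)
    n_match <- sum(a[both] == b[both])
    mism <- rownames(cls)[both & a != b]
    data.frame(donor = d, n_shared = n_shared, n_match = n_match,
               agreement_pct = if (n_shared) 100 * n_match / n_shared
                               else NA_real_,
               status = if (n_shared) "evaluated" else "unevaluable",
               mismatch_probes = paste(mism, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Donor-level array genotypes for one tissue
#'
#' Convenience wrapper around [array_genotypes()] that keeps one tissue's
#' columns and relabels the rows by donor id, ready for matching against
#' a sequencing-derived genotype matrix.
#'
#' @param bm a [beta_matrix()].
#' @param tissue tissue suffix to keep (default `"blood"`).
#' @param ... passed to [array_genotypes()].
#' @return A [genotype_matrix()] with donor ids as sample names.
#' @export
array_donor_genotypes <- function(bm, tissue = "blood", ...) {
  gm <- array_genotypes(bm, ...)
  suffix <- paste0("_", tissue, "$")
  keep <- grep(suffix, rownames(gm$calls))
  if (!length(keep)) stop("no sample columns for tissue ", tissue)
  gm$calls <- gm$calls[keep, , drop = FALSE]
  rownames(gm$calls) <- sub(suffix, "", rownames(gm$calls))
  gm
}
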