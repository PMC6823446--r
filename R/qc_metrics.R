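#' Coverage depth summary
#'
#' @param depths non-empty vector of non-negative integer per-position
#'   depths.
#' @param threshold depth cut-off for the covered fraction (default 30).
#' @return list: `median_depth` (lower median for even lengths, so the
#'   value is always an observed depth), `fraction_ge` (share of
#'   positions with depth >= threshold), `threshold`.
#' @examples
#' coverage_summary(c(1, 2, 3, 4, 100), threshold = 4)
#' @export
coverage_summary <- function(depths, threshold = 30) {
  if (length(depths) == 0) stop("depths must be non-empty")
  if (any(depths < 0)) stop("depths must be non-negative")
  s <- sort(depths)
  med <- s[ceiling(length(s) / 2)]            # lower median
  list(median_depth = med,
       fraction_ge = mean(depths >= threshold),
       threshold = threshold)
}

#' Read duplication and GC percentages
#'
#' @param n_duplicates,n_total duplicate and total read counts,
#'   `n_duplicates <= n_total`, `n_total > 0`.
#' @param base_counts named counts for A/C/G/T and optionally N; N is
#'   excluded from the GC denominator.
#' @return list: `duplication_pct`, `gc_pct`.
#' @export
read_stats <- function(n_duplicates, n_total, base_counts) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_duplicates > n_total) stop("more duplicates than reads")
  acgt <- base_counts[c("A", "C", "G", "T")]
  if (anyNA(acgt)) stop("base_counts needs entries A, C, G, T")
  if (sum(acgt) <= 0) stop("no A/C/G/T bases")
  list(duplication_pct = 100 * n_duplicates / n_total,
       gc_pct = 100 * sum(base_counts[c("G", "C")]) / sum(acgt))
}

#' Detection p-value and bead-count QC of a beta matrix
#'
#' Per sample column: the share of probes with an available detection
#' p-value, the share of available p-values below `p_cut`, the same pair
#' for bead counts against `bead_cut`, and the mean available bead
#' count. The pooled row is the unweighted mean over sample columns.
#'
#' @param bm a [beta_matrix()].
#' @param p_cut detection p threshold (default 0.01).
#' @param bead_cut minimum reliable bead count (default 3).
#' @return list: `per_sample` data.frame (one row per column plus the
#'   fractions as percentages) and `pooled` (named vector of column
#'   means).
#' @export
array_qc_summary <- function(bm, p_cut = 0.01, bead_cut = 3) {
  per <- lapply(colnames(bm$beta), function(cn) {
    p <- bm$detection_p[, cn]
    k <- bm$bead_count[, cn]
    data.frame(sample = cn,
               detp_available_pct = 100 * mean(!is.na(p)),
               detp_pass_pct = 100 * mean(p[!is.na(p)] < p_cut),
               beads_available_pct = 100 * mean(!is.na(k)),
               beads_pass_pct = 100 * mean(k[!is.na(k)] >= bead_cut),
               mean_bead_count = mean(k, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  pooled <- colMeans(per[, -1, drop = FALSE])
  list(per_sample = per, pooled = pooled)
}

#' Mean and range of a summary-table column
#'
#' @param x non-empty numeric vector.
#' @return list: `mean` (rounded to 2 decimals), `min`, `max`.
#' @examples
#' table_aggregate(c(8.8, 9.1, 9.2, 8.5, 8.3, 7.9, 8.7, 9.3, 8.6, 7.1))
#' @export
table_aggregate <- function(x) {
  if (length(x) == 0) stop("empty column")
  list(mean = round(mean(x), 2), min = min(x), max = max(x))
}
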