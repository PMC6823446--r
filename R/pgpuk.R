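#' Published QC and matching summary tables of the PGP-UK reference cohort
#'
#' Transcribed per-sample summary tables for the ten-donor PGP-UK pilot
#' multi-omics reference panel (WGS, WGBS, RNA-seq from blood; 450k
#' arrays from blood and saliva). These are summary-level inputs for the
#' package's aggregation functions and worked examples — the underlying
#' sequence-level data live in public archives and are not shipped.
#'
#' @return A list of data.frames:
#' * `wgs`, `wgbs`: `sample_id`, `median_coverage` (X),
#'   `pct_bases_ge_30x`, `dup_pct_r1`, `dup_pct_r2`, `gc_pct_r1`,
#'   `gc_pct_r2`.
#' * `rnaseq`: `sample_id`, `rin`, `uniquely_aligned_pct`, `dup_pct_r1`,
#'   `dup_pct_r2`, `gc_pct_r1`, `gc_pct_r2`.
#' * `array`: `sample_id`, `tissue`, `detp_available_pct`,
#'   `detp_pass_pct` (p < 0.01), `beads_available_pct`, `beads_pass_pct`
#'   (n >= 3).
#' * `matching`: long format — `sample_id`, `comparison` (one of
#'   `"WGS vs 450k"`, `"WGS vs WGBS"`, `"WGS vs RNA-seq"`), `loci_n`
#'   (shared loci used), `loci_pct` (of the 65- or 279-locus panel),
#'   `matched_pct`, and `n_match` recovered as
#'   `round(loci_n * matched_pct / 100)`.
#' @examples
#' tb <- pgpuk_qc_tables()
#' table_aggregate(tb$rnaseq$rin)
#' @export
pgpuk_qc_tables <- function() {
  ids <- c("uk35C650", "uk2E2AAE", "uk2DF242", "uk740176", "uk33D02F",
           "uk0C72FF", "uk1097F9", "uk174659", "uk85AA3B", "uk481F67")
  wgs <- data.frame(
    sample_id = ids,
    median_coverage = c(32, 47, 35, 35, 31, 31, 39, 35, 37, 30),
    pct_bases_ge_30x = c(64, 95, 75, 80, 58, 57, 85, 78, 85, 54),
    dup_pct_r1 = c(8.0, 18.3, 10.2, 8.3, 11.2, 3.7, 4.5, 8.5, 6.1, 8.6),
    dup_pct_r2 = c(6.3, 18.4, 13.6, 9.6, 12.1, 8.1, 12.7, 15.1, 3.2, 7.0),
    gc_pct_r1 = c(40, 41, 41, 40, 41, 41, 40, 41, 41, 41),
    gc_pct_r2 = c(41, 41, 41, 41, 41, 41, 41, 41, 41, 41),
    stringsAsFactors = FALSE)
  wgbs <- data.frame(
    sample_id = ids,
    median_coverage = c(10, 15, 16, 15, 16, 14, 14, 14, 16, 15),
    pct_bases_ge_30x = c(15, 20, 23, 20, 20, 18, 15, 17, 19, 25),
    dup_pct_r1 = c(27.3, 39.4, 28.0, 25.8, 26.3, 26.8, 26.0, 27.1, 28.3, 31.6),
    dup_pct_r2 = c(13.3, 20.3, 12.4, 12.6, 13.1, 11.4, 10.8, 15.5, 14.9, 17.4),
    gc_pct_r1 = c(26, 24, 24, 25, 24, 25, 24, 24, 24, 26),
    gc_pct_r2 = c(29, 27, 27, 27, 27, 28, 27, 27, 27, 29),
    stringsAsFactors = FALSE)
  rnaseq <- data.frame(
    sample_id = ids,
    rin = c(8.8, 9.1, 9.2, 8.5, 8.3, 7.9, 8.7, 9.3, 8.6, 7.1),
    uniquely_aligned_pct = c(88.8, 89.3, 90.0, 90.0, 87.0, 86.7, 86.1,
                             90.4, 89.0, 90.4),
    dup_pct_r1 = c(83.2, 85.9, 86.3, 84.8, 85.5, 85.0, 86.5, 84.4, 84.9, 87.3),
    dup_pct_r2 = c(80.6, 82.3, 81.9, 80.6, 82.6, 82.5, 82.6, 81.3, 81.2, 83.7),
    gc_pct_r1 = c(53, 53, 53, 53, 53, 53, 54, 53, 53, 52),
    gc_pct_r2 = c(56, 56, 56, 56, 56, 56, 57, 56, 56, 55),
    stringsAsFactors = FALSE)
  array <- data.frame(
    sample_id = rep(ids, each = 2),
    tissue = rep(c("blood", "saliva"), 10),
    detp_available_pct = rep(100, 20),
    detp_pass_pct = c(99.98476, 99.97899, 99.92297, 99.93491, 99.96478,
                      99.97178, 99.91638, 99.91638, 99.92791, 99.92771,
                      99.97467, 99.98558, 99.98929, 99.98744, 99.97714,
                      99.97899, 99.93327, 99.94089, 99.98126, 99.98105),
    beads_available_pct = c(99.91370, 99.93710, 99.92503, 99.93670,
                            99.90896, 99.92110, 99.90361, 99.91800,
                            99.91761, 99.93120, 99.90484, 99.88910,
                            99.92460, 99.92150, 99.94151, 99.92190,
                            99.89351, 99.91670, 99.91514, 99.92130),
    beads_pass_pct = rep(100, 20),
    stringsAsFactors = FALSE)
  matching <- rbind(
    data.frame(sample_id = ids, comparison = "WGS vs 450k",
               loci_n = rep(65L, 10), loci_pct = rep(100, 10),
               matched_pct = rep(100, 10), stringsAsFactors = FALSE),
    data.frame(sample_id = ids, comparison = "WGS vs WGBS",
               loci_n = c(52L, 51L, 58L, 61L, 53L, 57L, 54L, 52L, 60L, 53L),
               loci_pct = c(80, 78.46, 89.23, 93.85, 81.54, 87.69, 83.08,
                            80, 92.30, 81.54),
               matched_pct = c(100, 100, 100, 98.36, 100, 98.25, 98.15,
                               100, 100, 100), stringsAsFactors = FALSE),
    data.frame(sample_id = ids, comparison = "WGS vs RNA-seq",
               loci_n = c(161L, 172L, 183L, 152L, 188L, 159L, 190L, 197L,
                          167L, 169L),
               loci_pct = c(57.71, 61.65, 65.59, 54.48, 67.38, 56.99,
                            68.10, 70.61, 59.86, 60.57),
               matched_pct = c(81.99, 75.58, 70.49, 80.26, 69.68, 81.13,
                               73.68, 74.62, 83.23, 71.01),
               stringsAsFactors = FALSE))
  matching$n_match <- as.integer(round(matching$loci_n *
                                         matching$matched_pct / 100))
  list(wgs = wgs, wgbs = wgbs, rnaseq = rnaseq, array = array,
       matching = matching)
}
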