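#' Select RNA-seq-informative exonic loci
#'
#' RNA-seq only covers expressed exons, so the WGS-vs-RNA-seq comparison
#' panel keeps candidate loci that are (a) variant in the cohort — a
#' non-reference genotype (dosage >= 1) called in at least `min_samples`
#' WGS samples (or merely covered there, with
#' `presence_mode = "covered"`) — and (b) located inside one of the
#' `top_k` most expressed genes. The two filters are independent and
#' commute; the result is ordered by (chrom, pos).
#'
#' @param wgs a [genotype_matrix()] of WGS calls over the candidate loci.
#' @param expression per-gene expression: a data.frame with `gene_id`
#'   plus one or more sample value columns (aggregated by the mean), or a
#'   named numeric vector of already-aggregated values.
#' @param genes gene intervals: `GRanges` with `gene_id` (see
#'   [read_gene_bed()]) or a data.frame with `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param min_samples minimum qualifying WGS samples (default 4).
#' @param top_k expression rank cut-off (default 100); ranks tie-break by
#'   gene id.
#' @param presence_mode `"variant"` (default) or `"covered"`.
#' @return A [locus_panel()]; loci mapping to no gene are excluded. A
#'   locus overlapped by several genes is assigned to the first
#'   containing interval in (chrom, start) order.
#' @export
select_rnaseq_loci <- function(wgs, expression, genes, min_samples = 4L,
                               top_k = 100L,
                               presence_mode = c("variant", "covered")) {
  presence_mode <- match.arg(presence_mode)
  if (min_samples < 1 || top_k < 1)
    stop("min_samples and top_k must be >= 1")
  expr <- aggregate_expression(expression)
  if (is.data.frame(genes)) genes <- genes_granges(genes)
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)

  # filter (a): cohort presence in the WGS calls
  qual <- if (presence_mode == "variant") wgs$calls >= 1L
          else !is.na(wgs$calls)
  n_qual <- colSums(qual, na.rm = TRUE)
  present <- wgs$panel$id[n_qual >= min_samples]

  # filter (b): membership of a top-k expressed gene
  expr <- expr[names(expr) %in% genes$gene_id]
  ord <- order(-expr, names(expr))
  top_genes <- names(expr)[ord][seq_len(min(top_k, length(expr)))]
  loci_gr <- GenomicRanges::GRanges(
    seqnames = wgs$panel$chrom,
    ranges = IRanges::IRanges(start = wgs$panel$pos, width = 1L))
  hit <- GenomicRanges::findOverlaps(loci_gr, genes, select = "first")
  locus_gene <- setNames(genes$gene_id[hit], wgs$panel$id)
  in_top <- wgs$panel$id[!is.na(locus_gene) & locus_gene %in% top_genes]

  keep <- intersect(present, in_top)
  sel <- wgs$panel[wgs$panel$id %in% keep, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$pos), , drop = FALSE]
  locus_panel(sel$id, sel$chrom, sel$pos, sel$ref, sel$alt,
              name = "rnaseq_informative")
}

aggregate_expression <- function(expression) {
  if (is.numeric(expression) && !is.null(names(expression)))
    return(expression)
  if (is.data.frame(expression)) {
    if (!"gene_id" %in% names(expression))
      stop("expression data.frame needs a gene_id column")
    vals <- expression[setdiff(names(expression), "gene_id")]
    if (ncol(vals) == 0) stop("expression table has no value columns")
    return(setNames(rowMeans(as.matrix(vals)), expression$gene_id))
  }
  stop("expression must be a named vector or a gene_id data.frame")
}
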