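#' Read gene intervals from a BED file
#'
#' BED coordinates are 0-based half-open on disk; the returned `GRanges`
#' is 1-based inclusive, matching the convention used for loci throughout
#' the package. The BED name column (4th) supplies the gene id.
#'
#' @param path BED file (3+ columns).
#' @return A [GenomicRanges::GRanges] with metadata column `gene_id`.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name))
    gr$name <- paste0("gene", seq_along(gr))
  names(S4Vectors::mcols(gr))[names(S4Vectors::mcols(gr)) == "name"] <- "gene_id"
  gr
}

#' Write gene intervals as BED
#'
#' @param genes `GRanges` with a `gene_id` column, or a data.frame with
#'   `gene_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  if (is.data.frame(genes)) genes <- genes_granges(genes)
  d <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(genes)),
                  start = GenomicRanges::start(genes) - 1L,  # back to 0-based
                  end = GenomicRanges::end(genes),
                  name = genes$gene_id)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Gene data.frame to GRanges
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return `GRanges` with metadata column `gene_id`.
#' @export
genes_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end))
  gr$gene_id <- genes$gene_id
  gr
}
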