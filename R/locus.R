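#' Construct a locus panel
#'
#' A locus panel is the fixed set of biallelic genomic positions at which
#' every cross-modality comparison happens. Row order is preserved and is
#' part of the object's identity: downstream genotype matrices index their
#' columns by it.
#'
#' @param id character, unique locus identifiers (rs ids or synthetic ids).
#' @param chrom character, chromosome names.
#' @param pos integer, 1-based positions.
#' @param ref,alt single-letter reference / alternate alleles (A/C/G/T).
#' @param name panel label.
#' @return A `locus_panel`: a data.frame with columns `id`, `chrom`, `pos`,
#'   `ref`, `alt` and attribute `name`.
#' @examples
#' locus_panel(c("rs1", "rs2"), c("1", "2"), c(100L, 200L),
#'             c("A", "C"), c("G", "T"))
#' @export
locus_panel <- function(id, chrom, pos, ref, alt, name = "panel") {
  p <- data.frame(id = as.character(id), chrom = as.character(chrom),
                  pos = as.integer(pos), ref = as.character(ref),
                  alt = as.character(alt), stringsAsFactors = FALSE)
  validate_panel(p)
  attr(p, "name") <- name
  class(p) <- c("locus_panel", "data.frame")
  p
}

validate_panel <- function(p) {
  bases <- c("A", "C", "G", "T")
  bad <- which(!(p$ref %in% bases) | !(p$alt %in% bases))
  if (length(bad))
    stop("invalid allele letter at row ", bad[1])
  bad <- which(p$ref == p$alt)
  if (length(bad))
    stop("ref and alt alleles identical at row ", bad[1], " (", p$id[bad[1]], ")")
  if (anyDuplicated(p$id))
    stop("duplicate locus id: ", p$id[duplicated(p$id)][1])
  key <- paste(p$chrom, p$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom,pos): ", key[duplicated(key)][1])
  if (any(p$pos < 1)) stop("positions must be >= 1")
  invisible(p)
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("<locus_panel> ", attr(x, "name"), ": ", nrow(x), " loci\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more\n", sep = "")
  invisible(x)
}

#' Read a SNP-probe manifest
#'
#' The manifest ties each array SNP control probe to its genomic locus and
#' records which allele drives the beta-value towards 1
#' (`high_beta_allele`), the orientation needed to turn beta classes into
#' alt-allele dosages.
#'
#' @param path tab-delimited file with header columns `probe_id`, `id`,
#'   `chrom`, `pos`, `ref`, `alt`, `high_beta_allele`.
#' @return A `snp_manifest`: data.frame with those columns, file order
#'   preserved.
#' @seealso [manifest_panel()] for the implied locus panel.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("probe_id", "id", "chrom", "pos", "ref", "alt", "high_beta_allele")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  m <- m[need]
  m$pos <- as.integer(m$pos)
  as_manifest(m)
}

#' Build a manifest object from a data.frame
#'
#' @param m data.frame with manifest columns (see [read_manifest()]).
#' @return A validated `snp_manifest`.
#' @export
as_manifest <- function(m) {
  if (anyDuplicated(m$probe_id))
    stop("duplicate probe_id: ", m$probe_id[duplicated(m$probe_id)][1])
  bad <- which(!(m$high_beta_allele %in% c("ref", "alt")))
  if (length(bad))
    stop("high_beta_allele must be 'ref' or 'alt' at row ", bad[1])
  bases <- c("A", "C", "G", "T")
  bad <- which(!(m$ref %in% bases) | !(m$alt %in% bases) | m$ref == m$alt)
  if (length(bad))
    stop("invalid ref/alt alleles at row ", bad[1], " (", m$probe_id[bad[1]], ")")
  # panel-level invariants (unique ids, unique positions)
  invisible(locus_panel(m$id, m$chrom, m$pos, m$ref, m$alt))
  rownames(m) <- NULL
  class(m) <- c("snp_manifest", "data.frame")
  m
}

#' Write a SNP-probe manifest
#'
#' @param m a `snp_manifest`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Locus panel implied by a manifest
#'
#' @param m a `snp_manifest`.
#' @param name panel label.
#' @return A [locus_panel()] in manifest order.
#' @export
manifest_panel <- function(m, name = "array") {
  locus_panel(m$id, m$chrom, m$pos, m$ref, m$alt, name = name)
}
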