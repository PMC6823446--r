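#' Construct a genotype matrix
#'
#' Diploid genotypes are stored as alt-allele dosage (0, 1 or 2) relative
#' to the panel's reference allele; `NA` is the no-call sentinel and is
#' excluded from all concordance denominators.
#'
#' @param calls integer matrix, samples x loci; values in \{0, 1, 2, NA\}.
#'   Row names are sample ids, column names must equal `panel$id`.
#' @param panel a [locus_panel()].
#' @param modality one of `"wgs"`, `"wgbs"`, `"rnaseq"`, `"array"`.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, panel, modality) {
  modality <- match.arg(modality, c("wgs", "wgbs", "rnaseq", "array"))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(panel))
    stop("calls has ", ncol(calls), " columns but panel has ", nrow(panel), " loci")
  if (is.null(colnames(calls))) colnames(calls) <- panel$id
  if (!identical(colnames(calls), panel$id))
    stop("calls column names must match panel locus ids in order")
  if (nrow(calls) > 0 && is.null(rownames(calls)))
    stop("calls must have sample ids as row names")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  structure(list(calls = calls, panel = panel, modality = modality),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", x$modality, ": ", nrow(x$calls), " samples x ",
      ncol(x$calls), " loci; ", sum(is.na(x$calls)), " no-calls\n", sep = "")
  invisible(x)
}

#' Collapse dosage to zygosity
#'
#' @param dosage integer vector of alt-allele dosages (0/1/2/NA).
#' @return character vector: `"HOM"`, `"HET"` or `NA`.
#' @export
zygosity <- function(dosage) {
  out <- ifelse(dosage == 1L, "HET", "HOM")
  out[is.na(dosage)] <- NA_character_
  out
}

#' Read genotypes from a minimal VCF
#'
#' Consumes biallelic VCF 4.x records carrying a `GT` FORMAT field. The GT
#' strings `0/0`, `0/1` (or `1/0`), `1/1` and `./.` map to dosages 0, 1, 2
#' and no-call; phased separators (`|`) are accepted.
#'
#' @param path VCF file (plain text).
#' @param modality modality tag for the resulting matrix.
#' @return A [genotype_matrix()] whose panel is taken from the VCF
#'   CHROM/POS/ID/REF/ALT columns, record order preserved.
#' @export
read_genotype_vcf <- function(path, modality = "wgs") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF has no records: ", path)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multiallelic record at ", fix$CHROM[grep(",", fix$ALT)[1]], ":",
         fix$POS[grep(",", fix$ALT)[1]])
  panel <- locus_panel(fix$ID, fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) stop("VCF has no sample genotype columns")
  if (!all(grepl("(^|:)GT(:|$)", gt[, "FORMAT"])))
    stop("missing GT in FORMAT field")
  samples <- colnames(gt)[-1]
  gt_field <- vapply(seq_len(nrow(gt)), function(i) {
    which(strsplit(gt[i, "FORMAT"], ":", fixed = TRUE)[[1]] == "GT")
  }, integer(1))
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(fix),
                  dimnames = list(samples, panel$id))
  for (j in seq_along(samples)) {
    raw <- vapply(seq_len(nrow(gt)), function(i) {
      strsplit(gt[i, j + 1L], ":", fixed = TRUE)[[1]][gt_field[i]]
    }, character(1))
    calls[j, ] <- gt_to_dosage(raw)
  }
  genotype_matrix(calls, panel, modality)
}

gt_to_dosage <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[!is.na(gt) & gt == "0/0"] <- 0L
  out[!is.na(gt) & gt %in% c("0/1", "1/0")] <- 1L
  out[!is.na(gt) & gt == "1/1"] <- 2L
  known <- is.na(gt) | gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (!all(known)) stop("unrecognised GT value: ", gt[!known][1])
  out
}

#' Write genotypes as a minimal VCF
#'
#' Emits a deterministic, GT-only VCF 4.2: identical inputs produce
#' byte-identical files.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  p <- gm$panel
  dos_to_gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(gm$calls)), collapse = "\t"))
  body <- if (nrow(gm$calls) == 0) character(0) else
    vapply(seq_len(nrow(p)), function(i) {
    g <- gm$calls[, i]
    gt <- ifelse(is.na(g), "./.", dos_to_gt[as.character(g)])
      paste(c(p$chrom[i], p$pos[i], p$id[i], p$ref[i], p$alt[i], ".", ".", ".",
              "GT", gt), collapse = "\t")
    }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
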