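#' Construct an allele count table
#'
#' Strand-resolved read counts supporting the reference and alternate
#' allele at each (sample, locus), plus a bucket for any other base. The
#' two strand buckets are the bisulfite original-top (OT) and
#' original-bottom (OB) template strands; non-bisulfite protocols may put
#' all counts in one bucket. Absent rows mean zero coverage.
#'
#' @param df data.frame with columns `sample_id`, `locus_id`,
#'   `ref_count_ot`, `alt_count_ot`, `ref_count_ob`, `alt_count_ob`,
#'   `other_count` (non-negative integers).
#' @param protocol `"wgs"`, `"wgbs"` or `"rnaseq"`.
#' @param panel a [locus_panel()]; every `locus_id` must belong to it.
#' @return An `allele_count_table`.
#' @export
allele_count_table <- function(df, protocol, panel) {
  protocol <- match.arg(protocol, c("wgs", "wgbs", "rnaseq"))
  need <- c("sample_id", "locus_id", "ref_count_ot", "alt_count_ot",
            "ref_count_ob", "alt_count_ob", "other_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- df[need]
  cnt <- c("ref_count_ot", "alt_count_ot", "ref_count_ob", "alt_count_ob",
           "other_count")
  for (cc in cnt) {
    df[[cc]] <- as.integer(df[[cc]])
    if (anyNA(df[[cc]]) || any(df[[cc]] < 0L))
      stop("negative or missing count in column ", cc)
  }
  unk <- setdiff(df$locus_id, panel$id)
  if (length(unk)) stop("unknown locus id: ", unk[1])
  rownames(df) <- NULL
  structure(list(counts = df, protocol = protocol, panel = panel),
            class = "allele_count_table")
}

#' @export
print.allele_count_table <- function(x, ...) {
  cat("<allele_count_table> ", x$protocol, ": ", nrow(x$counts),
      " rows over ", length(unique(x$counts$sample_id)), " samples, panel of ",
      nrow(x$panel), " loci\n", sep = "")
  invisible(x)
}

#' Total read depth per row of an allele count table
#'
#' @param act an [allele_count_table()].
#' @return integer vector, one value per row (sum of all five buckets).
#' @export
count_depth <- function(act) {
  with(act$counts,
       ref_count_ot + alt_count_ot + ref_count_ob + alt_count_ob + other_count)
}

#' Read an allele count table from TSV
#'
#' @param path tab-delimited file with the columns listed in
#'   [allele_count_table()].
#' @param protocol protocol tag.
#' @param panel a [locus_panel()].
#' @return An [allele_count_table()].
#' @export
read_allele_counts <- function(path, protocol, panel) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  allele_count_table(df, protocol, panel)
}

#' Write an allele count table to TSV
#'
#' @param act an [allele_count_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(act, path) {
  write.table(act$counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
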