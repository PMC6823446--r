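#' Genotype concordance between two samples
#'
#' The denominator counts loci called in both samples; a match is an
#' equal alt-allele dosage, or an equal zygosity (HOM vs HET) in
#' `"zygosity"` mode — the coarser comparison needed when array classes
#' cannot be oriented to an allele. With no shared called loci the
#' percentage is undefined (`NA`), never 0.
#'
#' @param a,b integer dosage vectors over the same locus panel (`NA` =
#'   no-call).
#' @param mode `"dosage"` (default) or `"zygosity"`.
#' @return list: `n_shared`, `n_match`, `pct` (100 * n_match / n_shared,
#'   or `NA`).
#' @examples
#' pair_concordance(c(0, 1, 2, NA), c(0, 1, 1, 2))
#' @export
pair_concordance <- function(a, b, mode = c("dosage", "zygosity")) {
  mode <- match.arg(mode)
  if (length(a) != length(b))
    stop("genotype vectors must cover the same panel")
  both <- !is.na(a) & !is.na(b)
  if (mode == "zygosity") {
    a <- zygosity(a); b <- zygosity(b)
  }
  n_shared <- sum(both)
  n_match <- sum(a[both] == b[both])
  list(n_shared = n_shared, n_match = n_match,
       pct = if (n_shared > 0) 100 * n_match / n_shared else NA_real_)
}

#' All-pairs concordance between two genotype matrices
#'
#' @param A,B [genotype_matrix()] objects; their panels must share loci
#'   (the comparison runs over the intersection, in `A`'s panel order).
#' @param mode passed to [pair_concordance()].
#' @param label comparison label (default `"<A modality> vs <B modality>"`).
#' @return A `concordance_matrix`: list with `n_shared`, `n_match`, `pct`
#'   matrices (rows = samples of `A`, columns = samples of `B`), `label`,
#'   `mode`, `n_loci`.
#' @export
concordance_matrix <- function(A, B, mode = c("dosage", "zygosity"),
                               label = NULL) {
  mode <- match.arg(mode)
  shared <- intersect(A$panel$id, B$panel$id)
  if (length(shared) == 0) stop("panels share no loci")
  a <- A$calls[, shared, drop = FALSE]
  b <- B$calls[, shared, drop = FALSE]
  if (is.null(label)) label <- paste(A$modality, "vs", B$modality)
  dims <- list(rownames(a), rownames(b))
  n_shared <- matrix(0L, nrow(a), nrow(b), dimnames = dims)
  n_match <- n_shared
  pct <- matrix(NA_real_, nrow(a), nrow(b), dimnames = dims)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    cc <- pair_concordance(a[i, ], b[j, ], mode)
    n_shared[i, j] <- cc$n_shared
    n_match[i, j] <- cc$n_match
    pct[i, j] <- cc$pct
  }
  structure(list(n_shared = n_shared, n_match = n_match, pct = pct,
                 label = label, mode = mode, n_loci = length(shared)),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat("<concordance_matrix> ", x$label, " (", x$mode, ", ", x$n_loci,
      " loci)\n", sep = "")
  print(round(x$pct, 2), ...)
  invisible(x)
}

#' Confirm expected sample pairings or flag swaps
#'
#' A row sample is confirmed when its expected partner's cell is both the
#' strict row maximum and at least `threshold` percent; otherwise the row
#' is flagged together with the best-matching competitor — for a label
#' swap, the two affected rows flag each other. Rows whose paired cell is
#' undefined (no shared called loci) are unevaluable.
#'
#' @param cm a [concordance_matrix()].
#' @param pairing named character vector: row sample -> expected column
#'   sample. Defaults to identity on the row names.
#' @param threshold minimum matched percentage for confirmation. 90 is a
#'   sensible default for DNA-level comparisons (array/WGBS vs WGS);
#'   use ~60 for RNA-seq vs WGS, where allelic imbalance and dropout
#'   depress concordance.
#' @return data.frame of report rows: `sample_id`, `comparison`,
#'   `expected`, `best_match`, `loci_n`, `loci_pct`, `matched_pct`,
#'   `status` in \{confirmed, flagged, unevaluable\}.
#' @export
verify_identity <- function(cm, pairing = NULL, threshold = 90) {
  rows <- rownames(cm$pct)
  cols <- colnames(cm$pct)
  if (is.null(pairing)) pairing <- setNames(rows, rows)
  bad <- setdiff(names(pairing), rows)
  if (length(bad)) stop("pairing references unknown row sample: ", bad[1])
  bad <- setdiff(unname(pairing), cols)
  if (length(bad)) stop("pairing references unknown column sample: ", bad[1])
  out <- lapply(names(pairing), function(s) {
    expected <- pairing[[s]]
    v <- cm$pct[s, ]
    paired <- v[[expected]]
    best <- if (all(is.na(v))) NA_character_ else names(v)[which.max(v)]
    status <- if (is.na(paired)) "unevaluable"
      else if (!is.na(paired) && paired >= threshold &&
               sum(v >= paired, na.rm = TRUE) == 1) "confirmed"
      else "flagged"
    data.frame(sample_id = s, comparison = cm$label, expected = expected,
               best_match = if (status == "confirmed") expected else best,
               loci_n = cm$n_shared[s, expected],
               loci_pct = 100 * cm$n_shared[s, expected] / cm$n_loci,
               matched_pct = paired, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Macro and micro summary of a matching report
#'
#' The macro mean averages each sample's matched percentage; the micro
#' (pooled) agreement is 100 * sum(n_match) / sum(n_shared), weighting
#' samples by their shared-locus counts. Both are reported because "mean
#' agreement" figures in the field are ambiguous between the two; the
#' pooled value is also given floored at 2 decimals since truncation is
#' a common printing convention.
#'
#' @param rows data.frame with columns `loci_n` (shared called loci) and
#'   either `n_match` (matched loci) or `matched_pct`; e.g. the output of
#'   [verify_identity()] augmented with `n_match`, or a published summary
#'   table.
#' @param panel_size optional panel size, to report mean locus coverage.
#' @return list: `n` (rows), `macro_pct`, `micro_pct`, `micro_pct_floor`,
#'   `mean_loci_pct` (all percentages rounded to 2 decimals except the
#'   floored variant, truncated to 2), plus raw `total_shared`,
#'   `total_match`.
#' @export
summarize_matching <- function(rows, panel_size = NULL) {
  if (nrow(rows) == 0)
    return(list(n = 0L, macro_pct = NA_real_, micro_pct = NA_real_,
                micro_pct_floor = NA_real_, mean_loci_pct = NA_real_,
                total_shared = 0L, total_match = 0L))
  if (is.null(rows$n_match) && is.null(rows$matched_pct))
    stop("rows need an n_match or matched_pct column")
  if (is.null(rows$matched_pct))
    rows$matched_pct <- 100 * rows$n_match / rows$loci_n
  macro <- mean(rows$matched_pct, na.rm = TRUE)
  if (!is.null(rows$n_match)) {
    total_shared <- sum(rows$loci_n)
    total_match <- sum(rows$n_match)
    micro <- 100 * total_match / total_shared
  } else {
    total_shared <- sum(rows$loci_n)
    total_match <- NA_integer_
    micro <- NA_real_
  }
  list(n = nrow(rows),
       macro_pct = round(macro, 2),
       micro_pct = round(micro, 2),
       micro_pct_floor = floor(micro * 100) / 100,
       mean_loci_pct = if (is.null(panel_size)) NA_real_
                       else round(mean(100 * rows$loci_n / panel_size), 2),
       total_shared = total_shared, total_match = total_match)
}
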