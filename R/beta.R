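#' Construct a beta matrix
#'
#' Holds the SNP control-probe beta-values of a 450k run together with the
#' companion detection p-values and bead counts, for one or more tissues
#' per donor. Columns are `<donor>_<tissue>` ids; rows are probes in
#' manifest order. `NA` marks missing cells, which are excluded from every
#' downstream denominator.
#'
#' @param beta,detection_p,bead_count numeric matrices, probes x samples,
#'   sharing dimnames; beta and detection p in \[0,1\] where present.
#' @param manifest a `snp_manifest` (see [read_manifest()]); row order must
#'   match the matrices.
#' @return A `beta_matrix`.
#' @export
beta_matrix <- function(beta, detection_p, bead_count, manifest) {
  beta <- as.matrix(beta); detection_p <- as.matrix(detection_p)
  bead_count <- as.matrix(bead_count)
  if (!identical(dim(beta), dim(detection_p)) ||
      !identical(dim(beta), dim(bead_count)))
    stop("beta, detection_p and bead_count matrices must share dimensions")
  if (!identical(colnames(beta), colnames(detection_p)) ||
      !identical(colnames(beta), colnames(bead_count)))
    stop("sample columns differ between the three matrices")
  if (nrow(beta) != nrow(manifest))
    stop("matrix has ", nrow(beta), " rows but manifest has ",
         nrow(manifest), " probes")
  if (is.null(rownames(beta))) rownames(beta) <- manifest$probe_id
  if (!identical(rownames(beta), manifest$probe_id))
    stop("row names must match manifest probe_id order")
  b <- beta[!is.na(beta)]
  if (length(b) && (any(b < 0) || any(b > 1)))
    stop("beta-values outside [0,1]")
  p <- detection_p[!is.na(detection_p)]
  if (length(p) && (any(p < 0) || any(p > 1)))
    stop("detection p-values outside [0,1]")
  k <- bead_count[!is.na(bead_count)]
  if (length(k) && any(k < 0)) stop("negative bead counts")
  structure(list(beta = beta, detection_p = detection_p,
                 bead_count = bead_count, manifest = manifest),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("<beta_matrix> ", nrow(x$beta), " probes x ", ncol(x$beta),
      " sample columns (", paste(utils::head(colnames(x$beta), 4),
                                 collapse = ", "), " ...)\n", sep = "")
  invisible(x)
}

#' Read beta / detection-p / bead-count TSV matrices
#'
#' @param path_beta,path_detp,path_beads tab-delimited matrices with probe
#'   ids in the first column and `<donor>_<tissue>` sample columns; `NA`
#'   marks missing cells.
#' @param manifest a `snp_manifest`; every probe id in the files must be
#'   known to it.
#' @return A [beta_matrix()] with rows in manifest order.
#' @export
read_beta_matrix <- function(path_beta, path_detp, path_beads, manifest) {
  rd <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
  }
  b <- rd(path_beta); p <- rd(path_detp); k <- rd(path_beads)
  unk <- setdiff(rownames(b), manifest$probe_id)
  if (length(unk)) stop("unknown probe id: ", unk[1])
  if (!setequal(rownames(b), manifest$probe_id))
    stop("beta matrix is missing probes present in the manifest")
  ord <- manifest$probe_id
  beta_matrix(b[ord, , drop = FALSE], p[ord, , drop = FALSE],
              k[ord, , drop = FALSE], manifest)
}

#' Write a beta matrix to three TSV files
#'
#' @param bm a [beta_matrix()].
#' @param path_beta,path_detp,path_beads output paths.
#' @return The three paths, invisibly.
#' @export
write_beta_matrix <- function(bm, path_beta, path_detp, path_beads) {
  wr <- function(m, path) {
    d <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  }
  wr(bm$beta, path_beta); wr(bm$detection_p, path_detp)
  wr(bm$bead_count, path_beads)
  invisible(c(path_beta, path_detp, path_beads))
}

#' Donor and tissue of beta-matrix sample columns
#'
#' Splits `<donor>_<tissue>` column ids at the final underscore.
#'
#' @param bm a [beta_matrix()].
#' @return data.frame with columns `column`, `donor`, `tissue`.
#' @export
beta_samples <- function(bm) {
  cols <- colnames(bm$beta)
  donor <- sub("_[^_]+$", "", cols)
  tissue <- sub("^.*_", "", cols)
  data.frame(column = cols, donor = donor, tissue = tissue,
             stringsAsFactors = FALSE)
}
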