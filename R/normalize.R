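# Count normalization to the working scales used downstream.
# Library size is always the within-matrix column sum: the pipeline starts at
# count matrices and never sees aligner-reported totals.

#' log2 RPKM normalization
#'
#' Converts raw counts to `log2(count * 1e9 / (libsize * length_bp) + pseudocount)`
#' per cell, where `libsize` is the column sum of counts.
#'
#' @param counts Expression matrix on the `counts` scale.
#' @param genes Gene info table with `gene_id` and `length_bp` covering every
#'   gene in `counts`.
#' @param pseudocount Positive offset added before the log; default 1 so that
#'   zero counts map to exactly 0.
#' @return Expression matrix on the `log2rpkm` scale.
#' @export
log2_rpkm <- function(counts, genes, pseudocount = 1) {
  stopifnot(expr_scale(counts) == "counts")
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libsize == 0], collapse = ", "), call. = FALSE)
  }
  len <- genes$length_bp[match(rownames(counts), genes$gene_id)]
  if (anyNA(len)) {
    stop("missing gene length for: ",
         paste(rownames(counts)[is.na(len)], collapse = ", "), call. = FALSE)
  }
  rpkm <- sweep(counts / len, 2, libsize, "/") * 1e9
  out <- log2(rpkm + pseudocount)
  attr(out, "scale") <- "log2rpkm"
  out
}

#' Counts-per-million normalization
#'
#' @param counts Expression matrix on the `counts` scale.
#' @return Expression matrix on the `cpm` scale; columns sum to 1e6.
#' @export
cpm_normalize <- function(counts) {
  stopifnot(expr_scale(counts) == "counts")
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libsize == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(counts, 2, libsize, "/") * 1e6
  attr(out, "scale") <- "cpm"
  out
}

#' Drop weakly expressed genes
#'
#' Keeps genes whose row mean is at least `min_mean`, preserving row order.
#'
#' @param mat Expression matrix on any scale.
#' @param min_mean Minimum row mean to retain a gene.
#' @return Filtered expression matrix (same scale).
#' @export
filter_low_expression <- function(mat, min_mean) {
  keep <- rowMeans(mat) >= min_mean
  if (!any(keep)) stop("no genes pass the expression filter", call. = FALSE)
  out <- mat[keep, , drop = FALSE]
  attr(out, "scale") <- expr_scale(mat)
  out
}
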