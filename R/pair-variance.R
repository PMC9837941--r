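# Pair-variance statistic: how far a patient's relapse transcriptome moved
# from its matched primary, measured as Euclidean distance in the space of the
# top principal components of the most highly variable genes.

#' Select highly variable genes
#'
#' The `n_hvg` genes with the largest cross-sample variance. Ties are broken
#' by lexicographic gene id so the selection is deterministic.
#'
#' @param mat Expression matrix (typically log2 RPKM).
#' @param n_hvg Number of genes to keep (default 500).
#' @return Character vector of gene ids, highest variance first.
#' @export
select_hvg <- function(mat, n_hvg = 500) {
  if (n_hvg > nrow(mat)) {
    stop("n_hvg (", n_hvg, ") exceeds number of genes (", nrow(mat), ")", call. = FALSE)
  }
  v <- apply(mat, 1, var)
  ord <- order(-v, rownames(mat))
  rownames(mat)[ord[seq_len(n_hvg)]]
}

#' Principal-component scores of samples
#'
#' Genes are centered (and optionally unit-scaled) across samples; samples are
#' projected onto the top right singular directions. The sign of each
#' component is fixed by forcing its largest-magnitude gene loading positive,
#' so results are reproducible across SVD implementations.
#'
#' @param mat Expression matrix restricted to the genes of interest
#'   (genes x samples).
#' @param n_pcs Number of components to keep (default 3).
#' @param center Center each gene (default TRUE).
#' @param scale_genes Unit-scale each gene (default FALSE; HVG selection
#'   already emphasizes high-variance genes and scaling would undo it).
#' @return List with `scores` (samples x n_pcs matrix, columns `PC1`...)
#'   and `variance_pct` (percent variance explained per kept component).
#' @export
pca_scores <- function(mat, n_pcs = 3, center = TRUE, scale_genes = FALSE) {
  x <- t(mat)                                   # samples x genes
  x <- scale(x, center = center, scale = scale_genes)
  sv <- svd(x)
  pos <- sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1])
  if (n_pcs > pos) {
    stop("n_pcs (", n_pcs, ") exceeds matrix rank (", pos, ")", call. = FALSE)
  }
  flip <- vapply(seq_len(n_pcs), function(k) {
    load <- sv$v[, k]
    sign(load[which.max(abs(load))])
  }, numeric(1))
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs) %*% diag(flip, n_pcs)
  dimnames(scores) <- list(colnames(mat), paste0("PC", seq_len(n_pcs)))
  list(scores = scores,
       variance_pct = 100 * sv$d[seq_len(n_pcs)]^2 / sum(sv$d^2))
}

#' Primary-relapse distances in PC space
#'
#' @param scores Samples x PCs score matrix from [pca_scores()].
#' @param pairs Pair index tibble from [pair_index()].
#' @param weights Optional per-PC weights applied before the Euclidean norm
#'   (e.g. explained-variance proportions); default unweighted.
#' @return Tibble with `patient_id` and `distance`.
#' @export
pair_distances <- function(scores, pairs, weights = NULL) {
  missing <- pairs$patient_id[!(pairs$primary %in% rownames(scores) &
                                  pairs$relapse %in% rownames(scores))]
  if (length(missing)) {
    stop("scores lack samples for patient(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, ncol(scores))
  d <- vapply(seq_len(nrow(pairs)), function(i) {
    delta <- scores[pairs$primary[i], ] - scores[pairs$relapse[i], ]
    sqrt(sum((weights * delta)^2))
  }, numeric(1))
  tibble::tibble(patient_id = pairs$patient_id, distance = d)
}

#' Compare pair distances between patient groups
#'
#' Two-sided Welch (unequal-variance) t-tests; for more than two groups every
#' pairwise comparison is reported. Groups with fewer than two patients are
#' excluded with a warning.
#'
#' @param distances Tibble with `patient_id` and `distance`.
#' @param grouping Tibble with `patient_id` and `group` (any label column name
#'   is accepted via `group_col`).
#' @param group_col Name of the grouping column (default `"group"`).
#' @return Tibble, one row per comparison: group labels, sizes, means, `t`, `p`.
#' @export
compare_groups <- function(distances, grouping, group_col = "group") {
  df <- dplyr::inner_join(distances, grouping, by = "patient_id")
  df$group <- df[[group_col]]
  sizes <- table(df$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "),
            call. = FALSE)
    df <- df[!df$group %in% small, , drop = FALSE]
  }
  gs <- sort(unique(df$group))
  if (length(gs) < 2) stop("need at least two groups with n >= 2", call. = FALSE)
  combos <- utils::combn(gs, 2, simplify = FALSE)
  purrr::map_dfr(combos, function(gg) {
    x <- df$distance[df$group == gg[1]]
    y <- df$distance[df$group == gg[2]]
    tt <- stats::t.test(x, y, var.equal = FALSE)
    tibble::tibble(group1 = gg[1], group2 = gg[2],
                   n1 = length(x), n2 = length(y),
                   mean1 = mean(x), mean2 = mean(y),
                   t = unname(tt$statistic), p = tt$p.value)
  })
}

#' Correlate pair distances with a patient covariate
#'
#' @param distances Tibble with `patient_id` and `distance`.
#' @param covariate Tibble with `patient_id` and a numeric covariate column.
#' @param covariate_col Name of the covariate column.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble with `r`, `p`, `n`.
#' @export
correlate_covariate <- function(distances, covariate, covariate_col = "age_years",
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- dplyr::inner_join(distances, covariate, by = "patient_id")
  x <- df[[covariate_col]]
  keep <- is.finite(x) & is.finite(df$distance)
  x <- x[keep]; y <- df$distance[keep]
  if (length(x) < 3) stop("need at least 3 finite observations", call. = FALSE)
  if (sd(x) == 0) stop("covariate has zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pair-variance analysis of a cohort
#'
#' End-to-end wrapper: selects highly variable genes within the supplied
#' sample subset, computes PC scores, and measures per-patient primary-relapse
#' distances. Subsetting happens before HVG selection, so a subgroup analysis
#' is self-contained and does not depend on excluded samples.
#'
#' @param mat Expression matrix on the log2 RPKM scale.
#' @param ann Cohort annotation covering the samples of `mat`.
#' @param samples Optional character vector of sample ids to analyze
#'   (default: all annotated samples present in `mat`).
#' @param n_hvg,n_pcs,center,scale_genes See [select_hvg()] and [pca_scores()].
#' @param cohort_tag Label recording which subset was analyzed.
#' @return Object of class `pair_variance` with elements `scores` (tibble),
#'   `variance_pct`, `distances` (tibble), `pairs`, `cohort_tag`, `config`.
#' @export
pair_variance <- function(mat, ann, samples = NULL, n_hvg = 500, n_pcs = 3,
                          center = TRUE, scale_genes = FALSE, cohort_tag = "all") {
  if (is.null(samples)) samples <- intersect(ann$sample_id, colnames(mat))
  sub <- mat[, samples, drop = FALSE]
  hvg <- select_hvg(sub, min(n_hvg, nrow(sub)))
  pc <- pca_scores(sub[hvg, , drop = FALSE], n_pcs = n_pcs, center = center,
                   scale_genes = scale_genes)
  pairs <- pair_index(ann[ann$sample_id %in% samples, , drop = FALSE])
  dist <- pair_distances(pc$scores, pairs)
  structure(list(
    scores = tibble::as_tibble(pc$scores, rownames = "sample_id"),
    variance_pct = pc$variance_pct,
    distances = dist,
    pairs = pairs,
    cohort_tag = cohort_tag,
    config = list(n_hvg = n_hvg, n_pcs = n_pcs, center = center,
                  scale_genes = scale_genes)
  ), class = "pair_variance")
}

#' @export
print.pair_variance <- function(x, ...) {
  cat("Pair-variance analysis (", x$cohort_tag, "): ",
      nrow(x$distances), " pairs, ", x$config$n_hvg, " HVGs, ",
      x$config$n_pcs, " PCs\n", sep = "")
  cat("Variance explained (%):", paste(sprintf("%.1f", x$variance_pct), collapse = ", "), "\n")
  cat("Median pair distance:", sprintf("%.3f", median(x$distances$distance)), "\n")
  invisible(x)
}

#' @export
tidy.pair_variance <- function(x, ...) x$distances

#' @export
glance.pair_variance <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$distances),
    n_hvg = x$config$n_hvg,
    n_pcs = x$config$n_pcs,
    total_variance_pct = sum(x$variance_pct),
    median_distance = median(x$distances$distance),
    cohort = x$cohort_tag
  )
}

#' Plot PC scores with primary-relapse pairs connected
#'
#' @param object A `pair_variance` result.
#' @param ann Optional annotation tibble supplying `group` colors.
#' @param ... Unused.
#' @return A ggplot object: PC1 vs PC2, paired samples joined by dotted lines,
#'   axes labelled with explained-variance percentages.
#' @export
autoplot.pair_variance <- function(object, ann = NULL, ...) {
  sc <- object$scores
  seg <- dplyr::inner_join(
    dplyr::inner_join(object$pairs,
                      dplyr::rename_with(sc, ~ paste0(.x, "_p")),
                      by = c(primary = "sample_id_p")),
    dplyr::rename_with(sc, ~ paste0(.x, "_r")),
    by = c(relapse = "sample_id_r"))
  if (!is.null(ann)) {
    sc <- dplyr::left_join(sc, ann[, c("sample_id", "group", "timepoint")],
                           by = "sample_id")
    p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                          colour = .data$group,
                                          shape = .data$timepoint))
  } else {
    p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$PC1_p, y = .data$PC2_p,
                                       xend = .data$PC1_r, yend = .data$PC2_r),
                          linetype = "dotted", colour = "grey40",
                          inherit.aes = FALSE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (VP %.1f%%)", object$variance_pct[1]),
      y = sprintf("PC2 (VP %.1f%%)", object$variance_pct[2])) +
    ggplot2::theme_minimal()
}
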