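# Cell-composition analysis: build cell-type signatures from a labeled
# single-cell reference, deconvolve bulk profiles into subtype fractions by
# non-negative least squares, test paired primary-relapse shifts, and verify
# shift directions with a rank-based single-sample enrichment score.

#' Build a cell-type signature matrix from a labeled single-cell reference
#'
#' Per-type mean CPM profiles; marker genes are the top
#' `markers_per_type` genes per type by the margin between the type's log2
#' CPM mean and the best competing type. The signature rows are the union of
#' all marker lists.
#'
#' @param sc_counts Single-cell expression matrix (`counts` scale),
#'   genes x cells.
#' @param labels Character vector of cell-type labels, one per cell.
#' @param markers_per_type Markers retained per type (default 50).
#' @param min_cells Minimum cells required per type (default 20).
#' @return Object of class `signature_matrix`: `profile` (marker genes x
#'   types, CPM), `markers` (named list type -> marker genes).
#' @export
build_signature <- function(sc_counts, labels, markers_per_type = 50, min_cells = 20) {
  stopifnot(length(labels) == ncol(sc_counts))
  types <- sort(unique(labels))
  if (length(types) < 2) stop("need at least 2 cell types", call. = FALSE)
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    stop("cell type(s) below ", min_cells, " cells: ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  cpm <- cpm_normalize(expr_matrix(sc_counts, "counts"))
  type_mean <- vapply(types, function(tp) rowMeans(cpm[, labels == tp, drop = FALSE]),
                      numeric(nrow(cpm)))
  log_mean <- log2(type_mean + 1)
  markers <- lapply(types, function(tp) {
    margin <- log_mean[, tp] - apply(log_mean[, setdiff(types, tp), drop = FALSE], 1, max)
    ord <- order(-margin, rownames(log_mean))
    top <- ord[seq_len(min(markers_per_type, length(ord)))]
    top <- top[margin[top] > 0]
    rownames(log_mean)[top]
  })
  names(markers) <- types
  if (any(lengths(markers) == 0)) {
    stop("no discriminative marker genes for type(s): ",
         paste(types[lengths(markers) == 0], collapse = ", "), call. = FALSE)
  }
  rows <- sort(unique(unlist(markers)))
  profile <- type_mean[rows, , drop = FALSE]
  if (any(rowSums(profile) == 0)) {
    profile <- profile[rowSums(profile) > 0, , drop = FALSE]
  }
  structure(list(profile = profile, markers = markers), class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("Cell-type signature:", nrow(x$profile), "marker genes x",
      ncol(x$profile), "types (", paste(colnames(x$profile), collapse = ", "), ")\n")
  invisible(x)
}

#' Deconvolve bulk profiles into cell-type fractions by NNLS
#'
#' Per sample, solves `min || S f - b ||_2` subject to `f >= 0` over the
#' signature genes and renormalizes `f` to sum to one. Goodness of fit per
#' sample is the Pearson correlation between `log2(S f + 1)` and
#' `log2(b + 1)`; a permutation p-value is the fraction of random gene
#' relabelings of the bulk vector achieving at least the observed
#' correlation.
#'
#' Sequencing counts have roughly constant coefficient of variation, so the
#' least-squares rows are scaled by the inverse mean signature expression by
#' default (`weighting = "inverse_mean"`); this variance stabilization keeps
#' a handful of highly expressed genes from dominating the fit. Unweighted
#' NNLS is available with `weighting = "none"`.
#'
#' @param bulk Bulk expression matrix on the `cpm` scale.
#' @param sig `signature_matrix` from [build_signature()].
#' @param n_perm Number of permutations for the fit p-value (default 100;
#'   0 skips the permutation test).
#' @param weighting Row weighting of the least-squares system:
#'   `"inverse_mean"` (default) or `"none"`.
#' @return Object of class `deconv_result`: `fractions` (samples x types,
#'   rows sum to 1), `diagnostics` (tibble: `sample_id`, `residual_norm`,
#'   `r_fit`, `p_perm`), `genes_used`.
#' @export
deconvolve_nnls <- function(bulk, sig, n_perm = 100,
                            weighting = c("inverse_mean", "none")) {
  weighting <- match.arg(weighting)
  S_full <- sig$profile
  common <- intersect(rownames(S_full), rownames(bulk))
  if (length(common) < 0.5 * nrow(S_full)) {
    stop("fewer than 50% of signature genes present in bulk matrix", call. = FALSE)
  }
  if (length(common) < nrow(S_full)) {
    warning("dropping ", nrow(S_full) - length(common),
            " signature gene(s) absent from bulk", call. = FALSE)
  }
  S <- S_full[common, , drop = FALSE]
  w <- if (weighting == "inverse_mean") 1 / (rowMeans(S) + 1) else rep(1, nrow(S))
  Sw <- S * w
  fit_one <- function(b) {
    f <- pracma::lsqnonneg(Sw, b * w)$x
    list(f = f, resid = sqrt(sum((S %*% f - b)^2)))
  }
  types <- colnames(S)
  n_s <- ncol(bulk)
  fractions <- matrix(NA_real_, n_s, length(types),
                      dimnames = list(colnames(bulk), types))
  diag_rows <- vector("list", n_s)
  for (j in seq_len(n_s)) {
    b <- bulk[common, j]
    if (all(b == 0)) stop("all-zero bulk column: ", colnames(bulk)[j], call. = FALSE)
    obs <- fit_one(b)
    r_obs <- cor(log2(as.numeric(S %*% obs$f) + 1), log2(b + 1))
    p_perm <- NA_real_
    if (n_perm > 0) {
      r_perm <- vapply(seq_len(n_perm), function(i) {
        bp <- sample(b)
        fp <- fit_one(bp)
        cor(log2(as.numeric(S %*% fp$f) + 1), log2(bp + 1))
      }, numeric(1))
      p_perm <- mean(r_perm >= r_obs)
    }
    f <- obs$f
    fractions[j, ] <- if (sum(f) > 0) f / sum(f) else rep(1 / length(types), length(types))
    diag_rows[[j]] <- tibble::tibble(sample_id = colnames(bulk)[j],
                                     residual_norm = obs$resid,
                                     r_fit = r_obs, p_perm = p_perm)
  }
  structure(list(fractions = fractions,
                 diagnostics = dplyr::bind_rows(diag_rows),
                 genes_used = common),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat("Deconvolution:", nrow(x$fractions), "samples x", ncol(x$fractions),
      "cell types over", length(x$genes_used), "signature genes\n")
  cat("Mean fractions:", paste(sprintf("%s=%.3f", colnames(x$fractions),
                                       colMeans(x$fractions)), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.deconv_result <- function(x, ...) {
  tibble::as_tibble(x$fractions, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "cell_type", values_to = "fraction")
}

#' @export
glance.deconv_result <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$fractions), n_types = ncol(x$fractions),
                 n_genes = length(x$genes_used),
                 mean_r_fit = mean(x$diagnostics$r_fit))
}

#' Stacked-bar plot of estimated cell-type fractions
#' @param object A `deconv_result`.
#' @param ... Unused.
#' @return ggplot object.
#' @export
autoplot.deconv_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$sample_id, .data$fraction,
                                 fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative proportion", fill = "Cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Paired primary-relapse tests of cell-type fractions
#'
#' Per cell type and stratum (e.g. molecular group), a paired two-sided
#' t-test of relapse minus primary fractions. Strata with fewer than
#' `min_pairs` pairs are reported with `p = NA` and a warning.
#'
#' @param fracs Samples x cell types fraction matrix (or `deconv_result`).
#' @param pairs Pair index tibble.
#' @param strata Optional tibble with `patient_id` and `stratum`; default one
#'   stratum `"all"`.
#' @param min_pairs Minimum pairs for a test (default 3).
#' @return Tibble: `stratum`, `cell_type`, `n_pairs`, `mean_primary`,
#'   `mean_relapse`, `mean_diff`, `t`, `p`.
#' @export
compare_fractions <- function(fracs, pairs, strata = NULL, min_pairs = 3) {
  if (inherits(fracs, "deconv_result")) fracs <- fracs$fractions
  if (is.null(strata)) strata <- tibble::tibble(patient_id = pairs$patient_id,
                                                stratum = "all")
  pr <- dplyr::inner_join(pairs, strata, by = "patient_id")
  purrr::map_dfr(sort(unique(pr$stratum)), function(st) {
    sub <- pr[pr$stratum == st, , drop = FALSE]
    prim <- fracs[sub$primary, , drop = FALSE]
    rel <- fracs[sub$relapse, , drop = FALSE]
    too_small <- nrow(sub) < min_pairs
    if (too_small) {
      warning("stratum '", st, "' has fewer than ", min_pairs,
              " pairs; p set to NA", call. = FALSE)
    }
    purrr::map_dfr(colnames(fracs), function(ct) {
      d <- rel[, ct] - prim[, ct]
      if (!too_small && sd(d) > 0) {
        tt <- stats::t.test(d)
        tstat <- unname(tt$statistic); p <- tt$p.value
      } else if (!too_small) {
        tstat <- 0; p <- 1
      } else {
        tstat <- NA_real_; p <- NA_real_
      }
      tibble::tibble(stratum = st, cell_type = ct, n_pairs = nrow(sub),
                     mean_primary = mean(prim[, ct]), mean_relapse = mean(rel[, ct]),
                     mean_diff = mean(d), t = tstat, p = p)
    })
  })
}

#' Mean expression profiles by sample groups
#'
#' @param mat Expression matrix (log2 RPKM).
#' @param ann Cohort annotation.
#' @param by Annotation columns defining the profiles (default group and
#'   timepoint).
#' @return Genes x profiles matrix; profile names join the group levels with
#'   `"."`.
#' @export
mean_group_profiles <- function(mat, ann, by = c("group", "timepoint")) {
  ann <- ann[ann$sample_id %in% colnames(mat), , drop = FALSE]
  key <- do.call(paste, c(ann[by], sep = "."))
  profs <- vapply(sort(unique(key)), function(k) {
    rowMeans(mat[, ann$sample_id[key == k], drop = FALSE])
  }, numeric(nrow(mat)))
  profs
}

#' Rank-based single-sample enrichment scores
#'
#' For each profile, genes are ranked by decreasing value and a normalized
#' weighted Kolmogorov-Smirnov running sum is computed per gene set: inside
#' the set the running sum rises by `|value|^weight_exponent` (normalized),
#' outside it falls uniformly. The score is the largest-magnitude deviation,
#' signed. `weight_exponent = 0` gives the classical unweighted KS statistic.
#' Set members absent from the profiles are dropped; sets with fewer than
#' `min_size` present members are skipped with a warning.
#'
#' @param profiles Genes x profiles numeric matrix (e.g. group-mean log2 RPKM
#'   from [mean_group_profiles()]).
#' @param sets Named list of gene sets.
#' @param weight_exponent Weight on the ranking values inside the set
#'   (default 1).
#' @param min_size Minimum present members per set (default 3).
#' @return Tibble: `set`, `profile`, `score`, `n_members`.
#' @export
gsva_like_scores <- function(profiles, sets, weight_exponent = 1, min_size = 3) {
  genes <- rownames(profiles)
  purrr::imap_dfr(sets, function(members, nm) {
    present <- intersect(members, genes)
    if (length(present) < min_size) {
      warning("skipping set '", nm, "': fewer than ", min_size,
              " members present", call. = FALSE)
      return(tibble::tibble())
    }
    purrr::map_dfr(colnames(profiles), function(pr) {
      v <- profiles[, pr]
      ord <- order(-v, genes)
      ranked <- genes[ord]
      s <- v[ord]
      inset <- ranked %in% present
      w <- abs(s)^weight_exponent
      nr <- sum(w[inset])
      inc <- numeric(length(s))
      if (nr > 0) inc[inset] <- w[inset] / nr else inc[inset] <- 1 / sum(inset)
      n_out <- sum(!inset)
      inc[!inset] <- -1 / n_out
      running <- cumsum(inc)
      tibble::tibble(set = nm, profile = pr,
                     score = running[which.max(abs(running))],
                     n_members = length(present))
    })
  })
}
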