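# Pair-blocked moderated differential expression. Pair blocking is realized
# as within-pair differencing followed by a one-sample empirical-Bayes
# moderated t-test; for balanced pairs this is exactly the paired two-level
# linear model. Hyperparameters (d0, s0^2) are estimated by moment matching
# on log sample variances via digamma/trigamma identities.

#' Within-pair expression differences
#'
#' @param mat Expression matrix (log2 RPKM), genes x samples.
#' @param pairs Pair index tibble from [pair_index()].
#' @return Patients x genes matrix of relapse minus primary values.
#' @export
paired_differences <- function(mat, pairs) {
  missing <- pairs$patient_id[!(pairs$primary %in% colnames(mat) &
                                  pairs$relapse %in% colnames(mat))]
  if (length(missing)) {
    stop("expression matrix lacks samples for patient(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- t(mat[, pairs$relapse, drop = FALSE] - mat[, pairs$primary, drop = FALSE])
  rownames(d) <- pairs$patient_id
  d
}

# Newton inversion of the trigamma function, needed to solve
# trigamma(d0/2) = var of log-variance residuals for the prior df.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated paired t-statistics
#'
#' Given a patients x genes matrix of within-pair differences, shrinks
#' gene-wise variances toward a common prior. The prior degrees of freedom
#' `d0` and prior variance `s0^2` are estimated by matching the first two
#' moments of `log(s_g^2)` to the scaled-F model implied by normal errors:
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)` has mean
#' `log(s0^2) + digamma(d0/2) - log(d0/2)` and excess variance
#' `trigamma(d0/2)` over `trigamma(d_g/2)`. The posterior variance is
#' `(d0*s0^2 + d_g*s_g^2) / (d0 + d_g)` and the moderated t uses
#' `d0 + d_g` degrees of freedom (normal reference when `d0` is infinite).
#'
#' @param diffs Patients x genes numeric matrix of paired differences.
#' @return List with `fit` (class `ebayes_fit`: `d0`, `s0_sq`, `s_g_sq`,
#'   `d_g`, `n_pairs`) and `table` (tibble: `gene`, `log2fc`, `t_mod`,
#'   `df_total`, `p_raw`, `direction`).
#' @export
ebayes_moderated_t <- function(diffs) {
  n <- nrow(diffs)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (ncol(diffs) < 10) stop("need at least 10 genes to estimate hyperparameters", call. = FALSE)
  m_g <- colMeans(diffs)
  s_g_sq <- apply(diffs, 2, var)
  if (all(s_g_sq == 0)) stop("all gene variances are zero; degenerate input", call. = FALSE)
  d_g <- n - 1

  ok <- s_g_sq > 0
  e_g <- log(s_g_sq[ok]) - digamma(d_g / 2) + log(d_g / 2)
  e_mean <- mean(e_g)
  e_var <- var(e_g) - trigamma(d_g / 2)
  if (is.finite(e_var) && e_var > 0) {
    d0 <- 2 * trigamma_inverse(e_var)
    s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(e_mean)
  }

  s_post <- if (is.infinite(d0)) rep(s0_sq, length(s_g_sq)) else {
    (d0 * s0_sq + d_g * s_g_sq) / (d0 + d_g)
  }
  t_mod <- m_g / sqrt(s_post / n)
  df_total <- d0 + d_g
  p_raw <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod)) else {
    2 * stats::pt(-abs(t_mod), df = df_total)
  }

  fit <- structure(list(d0 = d0, s0_sq = s0_sq, s_g_sq = s_g_sq,
                        d_g = d_g, n_pairs = n),
                   class = "ebayes_fit")
  table <- tibble::tibble(
    gene = colnames(diffs),
    log2fc = unname(m_g),
    t_mod = unname(t_mod),
    df_total = df_total,
    p_raw = unname(p_raw),
    direction = ifelse(m_g > 0, "up_in_relapse", "down_in_relapse")
  )
  list(fit = fit, table = table)
}

#' @export
print.ebayes_fit <- function(x, ...) {
  cat("Empirical-Bayes variance moderation\n")
  cat("  pairs:", x$n_pairs, " genes:", length(x$s_g_sq), "\n")
  cat("  prior df d0:", format(x$d0, digits = 4),
      " prior variance s0^2:", format(x$s0_sq, digits = 4), "\n")
  invisible(x)
}

#' @export
glance.ebayes_fit <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq, n_pairs = x$n_pairs,
                 n_genes = length(x$s_g_sq))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement,
#' capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Call and rank differentially expressed genes
#'
#' @param table DGE tibble containing `gene`, `log2fc`, `p_adj`, `direction`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param top_k Size of the headline lists (default 20).
#' @return List with `up`, `down` (all significant genes by direction) and
#'   `top_up`, `top_down` (first `top_k` by ascending `p_adj`, then
#'   descending `|log2fc|`, then gene id).
#' @export
select_degs <- function(table, alpha = 0.05, top_k = 20) {
  rank_tbl <- function(df) {
    df[order(df$p_adj, -abs(df$log2fc), df$gene), , drop = FALSE]
  }
  sig <- table[!is.na(table$p_adj) & table$p_adj < alpha, , drop = FALSE]
  up <- rank_tbl(sig[sig$direction == "up_in_relapse", , drop = FALSE])
  down <- rank_tbl(sig[sig$direction == "down_in_relapse", , drop = FALSE])
  list(up = up$gene, down = down$gene,
       top_up = head(up$gene, top_k), top_down = head(down$gene, top_k))
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a hit list and each
#' gene set, with BH adjustment across sets.
#'
#' @param hits Character vector of hit gene ids (subset of `universe`).
#' @param sets Named list of gene sets (each a subset of `universe`), or a
#'   single character vector.
#' @param universe Character vector of all testable gene ids.
#' @return Tibble: `set`, `set_size`, `n_hits`, `overlap`, `fold_enrichment`,
#'   `p`, `p_adj`.
#' @export
ora_hypergeometric <- function(hits, sets, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!is.list(sets)) sets <- list(set = sets)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe", call. = FALSE)
  N <- length(unique(universe))
  n_hit <- length(unique(hits))
  res <- purrr::imap_dfr(sets, function(s, nm) {
    if (!all(s %in% universe)) stop("set '", nm, "' not a subset of the universe", call. = FALSE)
    K <- length(unique(s))
    ov <- length(intersect(unique(hits), unique(s)))
    p <- stats::phyper(ov - 1, K, N - K, n_hit, lower.tail = FALSE)
    fold <- if (n_hit > 0 && K > 0) (ov / n_hit) / (K / N) else NA_real_
    tibble::tibble(set = nm, set_size = K, n_hits = n_hit, overlap = ov,
                   fold_enrichment = fold, p = p)
  })
  res$p_adj <- bh_adjust(res$p)
  res
}

#' Pair-blocked differential expression for a cohort
#'
#' Convenience wrapper: restrict to the requested molecular groups (Groups 3
#' and 4 are merged by default, mirroring a non-SHH/non-WNT analysis), form
#' within-pair differences, run the moderated t-test, and BH-adjust.
#'
#' @param mat Expression matrix (log2 RPKM).
#' @param ann Cohort annotation.
#' @param groups Character vector of groups to include (default
#'   `c("G3", "G4")`).
#' @param alpha,top_k Passed to [select_degs()].
#' @return Object of class `paired_dge`: `table` (full DGE tibble with
#'   `p_adj`), `fit`, `degs`, `groups`, `n_pairs`.
#' @export
paired_dge <- function(mat, ann, groups = c("G3", "G4"), alpha = 0.05, top_k = 20) {
  keep <- ann[ann$group %in% groups, , drop = FALSE]
  pairs <- pair_index(keep)
  diffs <- paired_differences(mat, pairs)
  eb <- ebayes_moderated_t(diffs)
  tbl <- eb$table
  tbl$p_adj <- bh_adjust(tbl$p_raw)
  structure(list(table = tbl, fit = eb$fit,
                 degs = select_degs(tbl, alpha = alpha, top_k = top_k),
                 groups = groups, n_pairs = nrow(pairs)),
            class = "paired_dge")
}

#' @export
print.paired_dge <- function(x, ...) {
  cat("Paired DGE (", paste(x$groups, collapse = "+"), "): ",
      x$n_pairs, " pairs, ", nrow(x$table), " genes\n", sep = "")
  cat("  up in relapse:", length(x$degs$up),
      " down in relapse:", length(x$degs$down), "\n")
  invisible(x)
}

#' @export
tidy.paired_dge <- function(x, ...) x$table

#' @export
glance.paired_dge <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, n_genes = nrow(x$table),
                 n_up = length(x$degs$up), n_down = length(x$degs$down),
                 d0 = x$fit$d0, s0_sq = x$fit$s0_sq)
}
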