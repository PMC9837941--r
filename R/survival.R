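# Survival machinery: Kaplan-Meier, log-rank, expression-cutoff scanning with
# Bonferroni control, metagene scores, Cox models (Efron ties), and
# categorical association tests. Standard estimators are delegated to the
# survival package; the cutoff scan and metagene logic are study-specific.

check_records <- function(time, event) {
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("survival times must be finite and >= 0", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
}

#' Per-patient survival records from a cohort annotation
#'
#' One record per patient, read from the primary-sample rows. Records with a
#' missing time or event are dropped and their count reported.
#'
#' @param ann Cohort annotation tibble.
#' @param endpoint `"os"` or `"pfs"`.
#' @return Tibble: `patient_id`, `time`, `event`, plus `group` and
#'   `age_years` when present.
#' @export
survival_records <- function(ann, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_months")
  ecol <- paste0(endpoint, "_event")
  prim <- ann[ann$timepoint == "primary", , drop = FALSE]
  keep <- !is.na(prim[[tcol]]) & !is.na(prim[[ecol]])
  if (any(!keep)) {
    message("dropping ", sum(!keep), " record(s) with missing ", endpoint, " data")
  }
  prim <- prim[keep, , drop = FALSE]
  out <- tibble::tibble(patient_id = prim$patient_id,
                        time = prim[[tcol]], event = prim[[ecol]])
  for (col in intersect(c("group", "age_years", "m_stage"), colnames(prim))) {
    out[[col]] <- prim[[col]]
  }
  check_records(out$time, out$event)
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Numeric event/censoring times (months).
#' @param event 0/1 event indicators.
#' @return Tibble step function: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, `std_err` (Greenwood standard error of S).
#' @export
km_estimate <- function(time, event) {
  check_records(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "plain", se.fit = TRUE)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, survival = fit$surv,
                 std_err = fit$std.err * fit$surv)
}

#' Log-rank test between survival groups
#'
#' @param time,event Survival data.
#' @param group Group labels (>= 2 levels).
#' @return Tibble: `chi2`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  check_records(time, event)
  if (length(unique(group)) < 2) stop("need at least 2 groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  tibble::tibble(chi2 = sd$chisq, df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Expression-cutoff survival scan ("Kaplan scan")
#'
#' Tries every distinct expression value inside the quantile window as a
#' high/low cutoff (high group strictly above the cutoff), requiring at
#' least `min_group` patients on each side, and keeps the split minimizing
#' the raw log-rank p. Bonferroni correction multiplies by the number of
#' cutoffs actually tested. Because splits depend only on expression ranks,
#' the scan is invariant to monotone transforms of expression.
#'
#' @param expr Numeric expression values, one per record.
#' @param time,event Survival data aligned with `expr`.
#' @param quantile_window Quantile range of admissible cutoffs
#'   (default c(0.1, 0.9)).
#' @param min_group Minimum group size per side (default 5).
#' @return One-row tibble: `best_cutoff`, `logrank_chi2`, `p_raw`,
#'   `p_bonferroni`, `n_cutoffs_tested`, `direction` (+1 if high expression
#'   carries excess risk, -1 if protective; NA when no valid cutoff exists).
#' @export
kaplan_scan <- function(expr, time, event, quantile_window = c(0.1, 0.9),
                        min_group = 5) {
  check_records(time, event)
  if (sum(event) == 0) stop("no events; scan undefined", call. = FALSE)
  qs <- quantile(expr, quantile_window, names = FALSE)
  cuts <- sort(unique(expr))
  cuts <- cuts[cuts >= qs[1] & cuts <= qs[2]]
  cuts <- cuts[vapply(cuts, function(cc) {
    hi <- sum(expr > cc); lo <- sum(expr <= cc)
    hi >= min_group && lo >= min_group
  }, logical(1))]
  na_result <- tibble::tibble(best_cutoff = NA_real_, logrank_chi2 = NA_real_,
                              p_raw = NA_real_, p_bonferroni = NA_real_,
                              n_cutoffs_tested = 0L, direction = NA_real_)
  if (!length(cuts)) return(na_result)
  res <- purrr::map_dfr(cuts, function(cc) {
    hi <- expr > cc
    sd <- survival::survdiff(survival::Surv(time, event) ~ hi)
    p <- stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
    # index 2 of survdiff groups is hi = TRUE; excess observed events = risk
    dir <- sign(sd$obs[2] - sd$exp[2])
    tibble::tibble(cutoff = cc, chi2 = sd$chisq, p = p, direction = dir)
  })
  best <- res[which.min(res$p), ]
  tibble::tibble(best_cutoff = best$cutoff, logrank_chi2 = best$chi2,
                 p_raw = best$p,
                 p_bonferroni = min(1, best$p * nrow(res)),
                 n_cutoffs_tested = nrow(res), direction = best$direction)
}

#' Cutoff scan over many genes
#'
#' @param mat Expression matrix (log2 RPKM), samples matched to `records`
#'   via `sample_ids`.
#' @param sample_ids Sample ids aligned with the records.
#' @param time,event Survival data.
#' @param genes Genes to scan.
#' @param ... Passed to [kaplan_scan()].
#' @return Tibble, one row per gene, `gene` first.
#' @export
kaplan_scan_genes <- function(mat, sample_ids, time, event, genes, ...) {
  purrr::map_dfr(genes, function(g) {
    dplyr::bind_cols(tibble::tibble(gene = g),
                     kaplan_scan(mat[g, sample_ids], time, event, ...))
  })
}

#' Pool scan-significant genes into favorable/unfavorable metagenes
#'
#' Candidate genes come from the paired DGE top lists. A relapse-up gene
#' whose high expression carries excess risk (Bonferroni-significant) joins
#' the unfavorable metagene; a relapse-down gene whose high expression is
#' protective joins the favorable metagene.
#'
#' @param scan_up Scan tibble (from [kaplan_scan_genes()]) for relapse-up
#'   candidates.
#' @param scan_down Scan tibble for relapse-down candidates.
#' @param alpha Bonferroni-corrected significance threshold (default 0.05).
#' @return Object of class `metagene_set`: `unfavorable`, `favorable` gene
#'   vectors (possibly empty).
#' @export
build_metagene <- function(scan_up, scan_down, alpha = 0.05) {
  pick <- function(tbl, dir) {
    ok <- !is.na(tbl$p_bonferroni) & tbl$p_bonferroni < alpha &
      tbl$direction == dir
    tbl$gene[ok]
  }
  structure(list(unfavorable = pick(scan_up, 1),
                 favorable = pick(scan_down, -1)),
            class = "metagene_set")
}

#' @export
print.metagene_set <- function(x, ...) {
  cat("Metagenes: unfavorable", length(x$unfavorable),
      "gene(s); favorable", length(x$favorable), "gene(s)\n")
  invisible(x)
}

#' Per-sample metagene score
#'
#' Mean of z-scored (across samples) log2 RPKM over the member genes.
#' Zero-variance members are skipped.
#'
#' @param mat Expression matrix (log2 RPKM).
#' @param genes Member gene ids.
#' @return Named numeric vector, one score per sample.
#' @export
metagene_score <- function(mat, genes) {
  genes <- intersect(genes, rownames(mat))
  if (!length(genes)) stop("no metagene members present in matrix", call. = FALSE)
  sub <- mat[genes, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  sub <- sub[sds > 0, , drop = FALSE]
  if (!nrow(sub)) stop("all metagene members have zero variance", call. = FALSE)
  z <- (sub - rowMeans(sub)) / apply(sub, 1, sd)
  colMeans(z)
}

#' Cox proportional-hazards fit
#'
#' Efron tie handling; warns when events are fewer than five per covariate;
#' errors on non-convergence or separation (unbounded coefficients).
#'
#' @param data Data frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return Object of class `cox_fit`: `table` (tibble: `term`, `beta`, `HR`,
#'   `conf_low`, `conf_high`, `se`, `p`), `loglik`, `n`, `n_events`.
#' @export
cox_fit <- function(data, covariates) {
  check_records(data$time, data$event)
  n_ev <- sum(data$event)
  if (n_ev < 5 * length(covariates)) {
    warning("fewer than 5 events per covariate (", n_ev, " events, ",
            length(covariates), " covariates)", call. = FALSE)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron",
                         control = survival::coxph.control(iter.max = 50,
                                                           eps = 1e-9))
  if (!is.null(fit$info) && grepl("did not converge", paste(fit$info, collapse = " "))) {
    stop("Cox model did not converge", call. = FALSE)
  }
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 20)) {
    stop("Cox model separation: unbounded coefficient(s)", call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  tbl <- tibble::tibble(term = names(beta), beta = unname(beta),
                        HR = exp(unname(beta)),
                        conf_low = exp(unname(beta) - 1.96 * se),
                        conf_high = exp(unname(beta) + 1.96 * se),
                        se = unname(se),
                        p = 2 * stats::pnorm(-abs(unname(beta) / se)))
  structure(list(table = tbl, loglik = fit$loglik[2], n = fit$n,
                 n_events = fit$nevent),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit:", x$n, "subjects,", x$n_events, "events, loglik",
      sprintf("%.3f", x$loglik), "\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) x$table

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik)
}

#' Categorical association tests
#'
#' For each pair of annotation factors: Fisher's exact test when any
#' expected cell count is below 5, otherwise the chi-squared test.
#'
#' @param ann Data frame of per-patient factors.
#' @param factor_pairs List of 2-element character vectors naming factor
#'   columns.
#' @return Tibble: `factor1`, `factor2`, `test`, `statistic`, `p`.
#' @export
association_tests <- function(ann, factor_pairs) {
  purrr::map_dfr(factor_pairs, function(fp) {
    a <- ann[[fp[1]]]; b <- ann[[fp[2]]]
    keep <- !is.na(a) & !is.na(b)
    tab <- table(a[keep], b[keep])
    if (any(dim(tab) < 2)) {
      stop("factor '", fp[which(dim(tab) < 2)[1]], "' has a single level",
           call. = FALSE)
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab, simulate.p.value = (any(dim(tab) > 2)),
                               B = 1e4)
      tibble::tibble(factor1 = fp[1], factor2 = fp[2], test = "fisher",
                     statistic = NA_real_, p = ft$p.value)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      tibble::tibble(factor1 = fp[1], factor2 = fp[2], test = "chisq",
                     statistic = unname(ct$statistic), p = ct$p.value)
    }
  })
}

#' Kaplan-Meier plot by group
#'
#' @param time,event Survival data.
#' @param group Group labels.
#' @return ggplot step-curve object.
#' @export
plot_km <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  df <- purrr::map_dfr(sort(unique(group)), function(g) {
    km <- km_estimate(time[group == g], event[group == g])
    dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                     km[, c("time", "survival")]) |>
      dplyr::mutate(group = g)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}
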