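toy_signature <- function() {
  # six types with disjoint, strongly expressed marker blocks
  genes <- sprintf("g%03d", 1:120)
  types <- c("A1", "A2", "B1", "B2", "C1", "C2")
  S <- matrix(5, 120, 6, dimnames = list(genes, types))
  for (k in 1:6) S[((k - 1) * 20 + 1):(k * 20), k] <- 100
  structure(list(profile = S,
                 markers = split(genes, rep(types, each = 20))),
            class = "signature_matrix")
}

test_that("marker selection separates disjoint expression blocks", {
  set.seed(3)
  genes <- sprintf("g%03d", 1:60)
  counts <- matrix(rpois(60 * 80, 2), 60, 80,
                   dimnames = list(genes, sprintf("c%03d", 1:80)))
  labels <- rep(c("t1", "t2"), each = 40)
  counts[1:15, labels == "t1"] <- counts[1:15, labels == "t1"] + 80
  counts[16:30, labels == "t2"] <- counts[16:30, labels == "t2"] + 80
  sig <- build_signature(expr_matrix(counts, "counts"), labels,
                         markers_per_type = 15)
  expect_setequal(sig$markers$t1, genes[1:15])
  expect_setequal(sig$markers$t2, genes[16:30])

  # identical types have no discriminative genes
  flat <- matrix(5L, 60, 80, dimnames = dimnames(counts))
  expect_error(build_signature(expr_matrix(flat, "counts"), labels),
               "discriminative")
  expect_error(build_signature(expr_matrix(counts, "counts"),
                               rep(c("t1", "t2"), c(70, 10))), "below")
})

test_that("signature recovery finds the generating markers", {
  cfg <- small_config(seed = 9, n_genes = 1200)
  sc <- simulate_sc_reference(cfg)
  sig <- build_signature(sc$sc_counts, sc$labels, markers_per_type = 30)
  for (tp in colnames(sig$profile)) {
    # generating markers: genes upweighted for this type in the true signature
    true_m <- rownames(sc$signature)[sc$signature[, tp] >
                                       apply(sc$signature[, setdiff(colnames(sc$signature), tp)], 1, max)]
    expect_gte(mean(sig$markers[[tp]] %in% true_m), 0.8)
  }
  # per-type mean CPM correlates with the generating signature
  cpm <- cpm_normalize(sc$sc_counts)
  for (tp in unique(sc$labels)) {
    prof <- rowMeans(cpm[, sc$labels == tp, drop = FALSE])
    expect_gt(cor(prof, sc$signature[, tp] / sum(sc$signature[, tp])), 0.95)
  }
})

test_that("NNLS recovers exact mixtures and pure profiles", {
  sig <- toy_signature()
  f_true <- c(0.5, 0.5, 0, 0, 0, 0)
  bulk <- matrix(as.numeric(sig$profile %*% f_true), ncol = 1,
                 dimnames = list(rownames(sig$profile), "mix"))
  attr(bulk, "scale") <- "cpm"
  dec <- deconvolve_nnls(bulk, sig, n_perm = 0)
  expect_equal(unname(dec$fractions["mix", ]), f_true, tolerance = 1e-6)

  pure <- matrix(sig$profile[, "B1"], ncol = 1,
                 dimnames = list(rownames(sig$profile), "pure"))
  attr(pure, "scale") <- "cpm"
  dec2 <- deconvolve_nnls(pure, sig, n_perm = 0)
  expect_equal(unname(dec2$fractions["pure", "B1"]), 1, tolerance = 1e-6)

  # fractions invariant to global scaling of a bulk column
  dec3 <- deconvolve_nnls(bulk * 7, sig, n_perm = 0)
  expect_equal(dec3$fractions, dec$fractions, tolerance = 1e-8)

  # insufficient gene overlap is an error
  short <- bulk[1:40, , drop = FALSE]
  attr(short, "scale") <- "cpm"
  expect_error(suppressWarnings(deconvolve_nnls(short, sig, n_perm = 0)), "50%")
})

test_that("fractions are recovered on the simulated cohort", {
  cfg <- small_config(seed = 15, n_genes = 1200)
  sim <- simulate_cohort(cfg)
  sc <- simulate_sc_reference(cfg)
  sig <- build_signature(sc$sc_counts, sc$labels, markers_per_type = 50)
  dec <- deconvolve_nnls(cpm_normalize(sim$counts), sig, n_perm = 0)
  tf <- sim$truth$true_fractions
  fr <- dec$fractions[rownames(tf), ]
  expect_true(all(abs(rowSums(fr) - 1) < 1e-6))
  expect_lt(sqrt(mean((fr - tf)^2)), 0.05)
  for (ct in colnames(tf)) {
    expect_gt(cor(fr[, ct], tf[, ct], method = "spearman"), 0.9)
  }
})

test_that("permutation p-values flag real mixtures as non-random", {
  sig <- toy_signature()
  set.seed(33)
  f <- c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1)
  bulk <- matrix(as.numeric(sig$profile %*% f) * exp(rnorm(120, 0, 0.2)),
                 ncol = 1, dimnames = list(rownames(sig$profile), "s"))
  attr(bulk, "scale") <- "cpm"
  dec <- deconvolve_nnls(bulk, sig, n_perm = 50)
  expect_lte(dec$diagnostics$p_perm, 0.05)
})

test_that("paired fraction tests behave under identity, swap and small strata", {
  fr <- matrix(rep(c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1), 8), 8, 6, byrow = TRUE,
               dimnames = list(c(rbind(paste0("P", 1:4, "_P"), paste0("P", 1:4, "_R"))),
                               c("A1", "A2", "B1", "B2", "C1", "C2")))
  pairs <- tibble::tibble(patient_id = paste0("P", 1:4),
                          primary = paste0("P", 1:4, "_P"),
                          relapse = paste0("P", 1:4, "_R"))
  cmp <- compare_fractions(fr, pairs)
  expect_true(all(cmp$t == 0))
  expect_true(all(cmp$p == 1))

  set.seed(41)
  fr2 <- fr + matrix(runif(48, 0, 0.05), 8, 6)
  cmp_a <- compare_fractions(fr2, pairs)
  swapped <- tibble::tibble(patient_id = pairs$patient_id,
                            primary = pairs$relapse, relapse = pairs$primary)
  cmp_b <- compare_fractions(fr2, swapped)
  expect_equal(cmp_a$t, -cmp_b$t, tolerance = 1e-10)
  expect_equal(cmp_a$p, cmp_b$p, tolerance = 1e-10)

  strata <- tibble::tibble(patient_id = pairs$patient_id,
                           stratum = c("big", "big", "big", "small"))
  expect_warning(cmp_s <- compare_fractions(fr2, pairs, strata), "small")
  expect_true(all(is.na(cmp_s$p[cmp_s$stratum == "small"])))
})

test_that("enrichment scores behave at the extremes and match fgsea", {
  set.seed(51)
  v <- sort(rnorm(200, 5, 2), decreasing = TRUE)
  profiles <- matrix(v, ncol = 1,
                     dimnames = list(sprintf("g%03d", 1:200), "prof"))
  top_set <- rownames(profiles)[1:10]
  bottom_set <- rownames(profiles)[191:200]
  sc <- gsva_like_scores(profiles, list(top = top_set, bottom = bottom_set))
  expect_gt(sc$score[sc$set == "top"], 0)
  expect_lt(sc$score[sc$set == "bottom"], 0)

  # random sets are centred near zero under the unweighted (KS) statistic;
  # value weighting with all-positive profiles shifts random sets slightly
  # positive by construction, so the symmetry check uses exponent 0
  means <- vapply(1:200, function(i) {
    s <- sample(rownames(profiles), 15)
    gsva_like_scores(profiles, list(r = s), weight_exponent = 0)$score
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.07)

  skip_if_not_installed("fgsea")
  for (expo in c(0, 1)) {
    s <- sample(rownames(profiles), 25)
    ours <- gsva_like_scores(profiles, list(s = s), weight_exponent = expo)$score
    theirs <- fgsea::calcGseaStat(setNames(v, rownames(profiles)),
                                  selectedStats = match(s, rownames(profiles)),
                                  gseaParam = expo)
    expect_equal(ours, theirs, tolerance = 1e-10)
  }

  expect_warning(gsva_like_scores(profiles, list(tiny = top_set[1:2])), "tiny")
})
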