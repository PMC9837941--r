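make_diffs <- function(n_pairs, n_genes, seed = 1, mean = 0, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_pairs * n_genes, mean, sd), n_pairs, n_genes,
         dimnames = list(sprintf("P%03d", seq_len(n_pairs)),
                         sprintf("g%04d", seq_len(n_genes))))
}

test_that("paired differences equal relapse minus primary", {
  ann <- toy_annotation(5)
  m <- random_expr(20, 10, seed = 3)
  colnames(m) <- ann$sample_id
  pairs <- pair_index(ann)
  d <- paired_differences(m, pairs)
  expect_equal(dim(d), c(5, 20))
  oracle <- t(m[, pairs$relapse]) - t(m[, pairs$primary])
  expect_equal(unclass(d), unclass(oracle), ignore_attr = TRUE, tolerance = 1e-12)

  # identical timepoints give zeros; a uniform +1 shift gives ones
  m2 <- m
  m2[, pairs$relapse] <- m2[, pairs$primary]
  expect_true(all(paired_differences(m2, pairs) == 0))
  m2[1, pairs$relapse] <- m2[1, pairs$primary] + 1
  expect_equal(unname(paired_differences(m2, pairs)[, 1]), rep(1, 5))

  expect_error(paired_differences(m[, 1:9], pairs), "P005")
})

test_that("moderated t collapses to the prior-variance z-form when d0 is infinite", {
  # every gene has the same sample variance, so the log-variance spread is
  # zero and the prior df estimate diverges
  set.seed(5)
  base <- c(-1, 0, 1, 2)   # variance 5/3 for every permutation
  diffs <- vapply(1:50, function(g) sample(base), numeric(4))
  dimnames(diffs) <- list(paste0("P", 1:4), sprintf("g%03d", 1:50))
  res <- ebayes_moderated_t(diffs)
  expect_true(is.infinite(res$fit$d0))
  m_g <- colMeans(diffs)
  expect_equal(res$table$t_mod, unname(m_g / sqrt(res$fit$s0_sq / 4)),
               tolerance = 1e-10)
  expect_equal(res$table$p_raw, unname(2 * pnorm(-abs(res$table$t_mod))),
               tolerance = 1e-12)
})

test_that("moderated t agrees with the limma oracle", {
  skip_if_not_installed("limma")
  diffs <- make_diffs(8, 500, seed = 7, sd = rep(runif(500, 0.5, 2), each = 8))
  res <- ebayes_moderated_t(diffs)
  fit <- limma::lmFit(t(diffs), design = matrix(1, 8, 1))
  fit <- limma::eBayes(fit)
  expect_equal(res$fit$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(res$fit$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$table$t_mod, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(res$table$p_raw, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("hyperparameters are recovered from scaled-inv-chi2 simulations", {
  d0_true <- 4; s0_true <- 0.05
  est <- t(vapply(1:20, function(s) {
    set.seed(100 + s)
    n_genes <- 5000; n <- 10
    sigma2 <- d0_true * s0_true / rchisq(n_genes, d0_true)
    diffs <- vapply(sigma2, function(v) rnorm(n, 0, sqrt(v)), numeric(n))
    dimnames(diffs) <- list(paste0("P", 1:n), sprintf("g%05d", 1:n_genes))
    fit <- ebayes_moderated_t(diffs)$fit
    c(fit$d0, fit$s0_sq)
  }, numeric(2)))
  expect_lt(abs(median(est[, 1]) - d0_true) / d0_true, 0.15)
  expect_lt(abs(median(est[, 2]) - s0_true) / s0_true, 0.15)
})

test_that("swapping pair roles negates effects and preserves p-values", {
  diffs <- make_diffs(6, 100, seed = 11)
  a <- ebayes_moderated_t(diffs)
  b <- ebayes_moderated_t(-diffs)
  expect_equal(a$table$log2fc, -b$table$log2fc)
  expect_equal(a$table$t_mod, -b$table$t_mod)
  expect_equal(a$table$p_raw, b$table$p_raw)
})

test_that("moderation gains power over the ordinary paired t at few pairs", {
  set.seed(17)
  n <- 5; n_genes <- 2000; n_de <- 200
  sd_g <- sqrt(4 * 0.3 / rchisq(n_genes, 4))
  mu <- c(rep(1, n_de), rep(0, n_genes - n_de))
  diffs <- vapply(seq_len(n_genes),
                  function(g) rnorm(n, mu[g], sd_g[g]), numeric(n))
  dimnames(diffs) <- list(paste0("P", 1:n), sprintf("g%05d", 1:n_genes))
  mod <- ebayes_moderated_t(diffs)$table
  p_ord <- apply(diffs, 2, function(x) t.test(x)$p.value)
  hits_mod <- which(bh_adjust(mod$p_raw) < 0.05)
  hits_ord <- which(bh_adjust(p_ord) < 0.05)
  expect_gte(sum(hits_mod <= n_de), sum(hits_ord <= n_de))
  expect_gt(sum(hits_mod <= n_de), 0)
})

test_that("BH adjustment matches closed forms and the reference oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(23)
  p <- runif(200)^2
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG selection orders by significance then effect then id", {
  tbl <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    log2fc = c(2, -1, 3, 0.5, -2),
    p_adj = c(0.01, 0.01, 0.001, 0.2, 0.04),
    direction = c("up_in_relapse", "down_in_relapse", "up_in_relapse",
                  "up_in_relapse", "down_in_relapse"))
  degs <- select_degs(tbl, alpha = 0.05, top_k = 1)
  expect_equal(degs$up, c("g3", "g1"))
  expect_equal(degs$down, c("g2", "g5"))
  expect_equal(degs$top_up, "g3")

  none <- select_degs(dplyr::mutate(tbl, p_adj = 0.9))
  expect_length(none$up, 0)
  expect_length(none$down, 0)
})

test_that("hypergeometric ORA matches exhaustive enumeration", {
  universe <- paste0("g", 1:4)
  out <- ora_hypergeometric(c("g1", "g2"), list(s = c("g1", "g2")), universe)
  expect_equal(out$p, 1 / 6, tolerance = 1e-12)

  out0 <- ora_hypergeometric(c("g1", "g2"), list(s = c("g3", "g4")), universe)
  expect_equal(out0$overlap, 0)
  expect_equal(out0$p, 1, tolerance = 1e-12)

  # brute force over all possible hit draws for small universes
  set.seed(31)
  for (i in 1:5) {
    N <- sample(8:12, 1)
    universe <- paste0("g", seq_len(N))
    set_g <- sample(universe, sample(2:5, 1))
    hits <- sample(universe, sample(2:5, 1))
    ov <- length(intersect(hits, set_g))
    draws <- utils::combn(N, length(hits))
    in_set <- seq_len(N) %in% match(set_g, universe)
    p_brute <- mean(apply(draws, 2, function(d) sum(in_set[d]) >= ov))
    out <- ora_hypergeometric(hits, list(s = set_g), universe)
    expect_equal(out$p, p_brute, tolerance = 1e-12)
  }
  expect_error(ora_hypergeometric("g1", list(s = "g1"), character(0)), "universe")
})

test_that("programmed DE genes are recovered at strong effect", {
  cfg <- small_config(seed = 51, n_genes = 1500, n_de_genes = 50, de_log2fc = 2)
  sim <- simulate_cohort(cfg)
  lrpkm <- log2_rpkm(sim$counts, sim$gene_info)
  dge <- paired_dge(lrpkm, sim$annotation, groups = c("SHH", "G3", "G4"))
  called <- c(dge$degs$up, dge$degs$down)
  recall <- mean(sim$truth$true_de_genes$gene %in% called)
  expect_gte(recall, 0.9)
  # direction concordance for recovered genes
  hit <- sim$truth$true_de_genes[sim$truth$true_de_genes$gene %in% called, ]
  dir <- dge$table$direction[match(hit$gene, dge$table$gene)]
  expect_gt(mean((hit$sign > 0) == (dir == "up_in_relapse")), 0.95)
})
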