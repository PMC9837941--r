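# Synthetic paired primary-relapse cohort generator. Bulk samples are
# negative-binomial counts around library-size-scaled mixtures of cell-type
# signature profiles, with Dirichlet-drawn fractions per sample. Relapse
# samples carry programmed composition shifts (via the relapse Dirichlet
# parameters), a designated set of differentially expressed genes, and, for a
# subset of pairs, a contiguous CNV-block expression effect. Survival times
# follow an exponential proportional-hazards model driven by an unfavorable
# metagene; both samples of a patient share SNP genotypes.

CELL_TYPES <- c("A1", "A2", "B1", "B2", "C1", "C2")

# Per-group Dirichlet parameters. The relative profile gives each molecular
# group a distinct dominant compartment (progenitor-rich SHH, cell-cycle-rich
# Group 3, differentiated-rich Group 4); the concentration (total mass 40) is
# set so that a programmed 1.5x mean shift of one subtype is detectable by a
# paired t-test at the cohort's smallest per-group sample size (analytic
# power ~0.9 at n = 14 pairs).
default_alpha_primary <- function() {
  list(SHH = c(A1 = 5.0, A2 = 5.0, B1 = 10.0, B2 = 6.5, C1 = 7.0, C2 = 6.5),
       G3  = c(A1 = 10.0, A2 = 6.5, B1 = 6.5, B2 = 5.0, C1 = 5.0, C2 = 7.0),
       G4  = c(A1 = 6.5, A2 = 6.5, B1 = 5.0, B2 = 5.0, C1 = 10.0, C2 = 7.0))
}

# Relapse parameters keep each group's total Dirichlet mass equal to the
# primary total, so a targeted alpha ratio translates exactly into the same
# ratio of expected fractions. Targets: progenitor (B1) gain and
# differentiated (C1) loss in SHH; cell-cycle (A1) gain (1.5x) and C1 loss
# in Groups 3/4; remaining types absorb the mass difference uniformly.
default_alpha_relapse <- function() {
  shift <- function(alpha, targets) {
    new <- alpha
    new[names(targets)] <- alpha[names(targets)] * targets
    rest <- setdiff(names(alpha), names(targets))
    new[rest] <- alpha[rest] * (sum(alpha) - sum(new[names(targets)])) / sum(alpha[rest])
    new
  }
  p <- default_alpha_primary()
  list(SHH = shift(p$SHH, c(B1 = 1.5, C1 = 0.6)),
       G3  = shift(p$G3,  c(A1 = 1.5, C1 = 0.6)),
       G4  = shift(p$G4,  c(A1 = 1.5, C1 = 0.6)))
}

#' Configuration for the synthetic paired cohort
#'
#' Defaults emulate the cohort structure the analysis assumes: 43 patients in
#' three molecular groups (24 SHH, 5 Group 3, 14 Group 4), two timepoints per
#' patient, six cell subtypes (cell-cycle A1/A2, progenitor B1/B2,
#' differentiated neuronal-like C1/C2), a 1.5-fold relapse gain of the
#' cell-cycle subtype in Groups 3/4 and a progenitor gain with
#' differentiated-cell loss in SHH, plus survival outcomes tied to an
#' unfavorable metagene.
#'
#' @param n_patients_per_group Named counts per molecular group.
#' @param n_genes Number of genes.
#' @param cell_types Cell-type labels (default the six subtypes).
#' @param dirichlet_alpha_primary,dirichlet_alpha_relapse Per-group named
#'   lists of Dirichlet parameters over cell types.
#' @param n_de_genes Number of programmed differentially expressed genes
#'   (half up, half down at relapse).
#' @param de_log2fc Programmed absolute log2 fold change.
#' @param nb_dispersion Negative-binomial size parameter.
#' @param libsize_range Range of per-sample library sizes.
#' @param cnv_block_effect Multiplicative expression shift on the CNV block.
#' @param cnv_pair_fraction Fraction of pairs receiving a relapse-only CNV
#'   block.
#' @param survival_baseline_scale Baseline exponential scale (months).
#' @param survival_metagene_loghr Log hazard ratio per SD of the unfavorable
#'   metagene score.
#' @param censor_rate Probability a subject is censored before the event.
#' @param n_snp_sites Number of fingerprint SNP sites.
#' @param cells_per_type Cells per type in the single-cell reference.
#' @param seed Integer RNG seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients_per_group = c(SHH = 24, G3 = 5, G4 = 14),
                              n_genes = 2000,
                              cell_types = CELL_TYPES,
                              dirichlet_alpha_primary = default_alpha_primary(),
                              dirichlet_alpha_relapse = default_alpha_relapse(),
                              n_de_genes = 100,
                              de_log2fc = 1.5,
                              nb_dispersion = 8,
                              libsize_range = c(5e5, 1.5e6),
                              cnv_block_effect = 1.6,
                              cnv_pair_fraction = 0.5,
                              survival_baseline_scale = 60,
                              survival_metagene_loghr = 0.8,
                              censor_rate = 0.3,
                              n_snp_sites = 200,
                              cells_per_type = 120,
                              seed = 1L) {
  cfg <- list(n_patients_per_group = n_patients_per_group, n_genes = n_genes,
              cell_types = cell_types,
              dirichlet_alpha_primary = dirichlet_alpha_primary,
              dirichlet_alpha_relapse = dirichlet_alpha_relapse,
              n_de_genes = n_de_genes, de_log2fc = de_log2fc,
              nb_dispersion = nb_dispersion, libsize_range = libsize_range,
              cnv_block_effect = cnv_block_effect,
              cnv_pair_fraction = cnv_pair_fraction,
              survival_baseline_scale = survival_baseline_scale,
              survival_metagene_loghr = survival_metagene_loghr,
              censor_rate = censor_rate, n_snp_sites = n_snp_sites,
              cells_per_type = cells_per_type, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  k <- length(cfg$cell_types)
  stopifnot(all(cfg$n_patients_per_group > 0), cfg$n_genes > 0, k > 0,
            cfg$n_snp_sites > 0, cfg$nb_dispersion > 0,
            length(cfg$libsize_range) == 2, all(cfg$libsize_range > 0))
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1) {
    stop("censor_rate must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_de_genes > cfg$n_genes) {
    stop("n_de_genes exceeds n_genes", call. = FALSE)
  }
  if (max(1L, round(0.05 * cfg$n_genes)) > cfg$n_genes) {
    stop("CNV block size exceeds n_genes", call. = FALSE)
  }
  for (nm in names(cfg$n_patients_per_group)) {
    for (side in c("dirichlet_alpha_primary", "dirichlet_alpha_relapse")) {
      a <- cfg[[side]][[nm]]
      if (is.null(a) || length(a) != k || any(a <= 0)) {
        stop(side, " for group ", nm, " must be a strictly positive vector of length ",
             k, call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic cohort config:",
      sum(x$n_patients_per_group), "patients (",
      paste(sprintf("%s=%d", names(x$n_patients_per_group), x$n_patients_per_group),
            collapse = ", "), "),",
      x$n_genes, "genes,", length(x$cell_types), "cell types, seed", x$seed, "\n")
  invisible(x)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# Shared gene model: ids, lengths, synthetic chromosomes (contiguous
# round-robin blocks over 22 chromosomes), cell-type signature profiles with
# dedicated marker genes, the programmed DE gene set and the CNV block.
# Drawn first under the config seed so the bulk cohort and the single-cell
# reference agree on the generative signatures.
make_gene_model <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  k <- length(cfg$cell_types)
  gene_ids <- sprintf("g%05d", seq_len(n))
  chrom <- paste0("chr", rep(1:22, each = ceiling(n / 22))[seq_len(n)])
  length_bp <- round(exp(runif(n, log(300), log(30000))))
  base <- stats::rlnorm(n, meanlog = 1.5, sdlog = 1.2)
  n_marker <- max(10L, round(0.04 * n))
  marker_pool <- sample(gene_ids, min(n, n_marker * k))
  marker_sets <- split(marker_pool, rep(cfg$cell_types,
                                        length.out = length(marker_pool)))
  sig <- matrix(base, n, k, dimnames = list(gene_ids, cfg$cell_types))
  for (tp in cfg$cell_types) {
    sig[marker_sets[[tp]], tp] <- sig[marker_sets[[tp]], tp] * 8
  }
  # programmed DE genes: outside marker sets so expression and composition
  # signals stay separable
  de_pool <- setdiff(gene_ids, marker_pool)
  de_genes <- sample(de_pool, min(cfg$n_de_genes, length(de_pool)))
  de_sign <- rep(c(1, -1), length.out = length(de_genes))
  block_size <- max(1L, round(0.05 * n))
  chrom_sizes <- table(chrom)
  eligible <- names(chrom_sizes)[chrom_sizes >= block_size]
  cnv_chrom <- if (length(eligible)) sample(eligible, 1) else names(which.max(chrom_sizes))
  on_chrom <- which(chrom == cnv_chrom)
  start <- on_chrom[1] + sample.int(max(1L, length(on_chrom) - block_size + 1L), 1) - 1L
  cnv_block <- gene_ids[start:min(n, start + block_size - 1L)]
  list(gene_ids = gene_ids, chrom = chrom, length_bp = length_bp,
       signature = sig, marker_sets = marker_sets,
       de_genes = de_genes, de_sign = de_sign, cnv_block = cnv_block)
}

sample_counts <- function(expected, libsize, size) {
  p <- expected / sum(expected)
  mu <- libsize * p
  stats::rnbinom(length(mu), mu = mu, size = size)
}

#' Simulate a paired primary-relapse cohort
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (expression matrix, `counts` scale),
#'   `gene_info` (tibble), `annotation` (tibble), `vaf` (sites x samples
#'   matrix) and `truth` (generating quantities: per-sample true fractions,
#'   DE genes with signs, metagene log HR, pair assignments, CNV pairs and
#'   block, SNP genotypes, signatures, analytic expected fraction ratios).
#' @export
simulate_cohort <- function(config) {
  validate_config(config)
  gm <- make_gene_model(config)
  cfg <- config
  groups <- rep(names(cfg$n_patients_per_group), cfg$n_patients_per_group)
  n_pat <- length(groups)
  patient_id <- sprintf("P%03d", seq_len(n_pat))

  # clinical covariates
  age <- vapply(groups, function(g) {
    if (g == "SHH") {
      if (runif(1) < 0.45) max(0.3, rnorm(1, 2.5, 1)) else max(15, rnorm(1, 26, 8))
    } else {
      min(18, max(1, rnorm(1, 8, 3)))
    }
  }, numeric(1))
  sex <- sample(c("M", "F"), n_pat, replace = TRUE, prob = c(0.65, 0.35))
  relapse_pattern <- vapply(groups, function(g) {
    p <- switch(g,
                SHH = c(local = 0.5, distant = 1 / 6, combined = 1 / 3),
                G3 = c(local = 0, distant = 0.7, combined = 0.3),
                c(local = 0, distant = 0.5, combined = 0.5))
    sample(names(p), 1, prob = p)
  }, character(1))
  m_stage <- vapply(relapse_pattern, function(rp) {
    p_adv <- c(local = 0.1, distant = 0.3, combined = 0.4)[rp]
    sample(c("M0-1", "M2-3"), 1, prob = c(1 - p_adv, p_adv))
  }, character(1))
  subgroup <- vapply(seq_len(n_pat), function(i) {
    switch(groups[i],
           SHH = if (age[i] < 5) "SHH_INF" else "SHH_CH_AD",
           G3 = sample(c("II", "III"), 1),
           sample(c("V", "VII", "VIII"), 1))
  }, character(1))
  novel_cnv <- as.integer(runif(n_pat) < cfg$cnv_pair_fraction)
  cnv_pairs <- patient_id[novel_cnv == 1]

  # per-sample fractions and counts
  sample_id <- c(rbind(paste0(patient_id, "_P"), paste0(patient_id, "_R")))
  k <- length(cfg$cell_types)
  fractions <- matrix(NA_real_, 2 * n_pat, k,
                      dimnames = list(sample_id, cfg$cell_types))
  counts <- matrix(0L, cfg$n_genes, 2 * n_pat,
                   dimnames = list(gm$gene_ids, sample_id))
  de_mult <- rep(1, cfg$n_genes)
  names(de_mult) <- gm$gene_ids
  de_mult[gm$de_genes] <- 2^(gm$de_sign * cfg$de_log2fc)
  relapse_score <- numeric(n_pat)   # metagene driver, from expected expression
  up_genes <- gm$de_genes[gm$de_sign > 0]

  for (i in seq_len(n_pat)) {
    g <- groups[i]
    f_p <- as.numeric(rdirichlet(1, cfg$dirichlet_alpha_primary[[g]]))
    f_r <- as.numeric(rdirichlet(1, cfg$dirichlet_alpha_relapse[[g]]))
    fractions[2 * i - 1, ] <- f_p
    fractions[2 * i, ] <- f_r
    exp_p <- as.numeric(gm$signature %*% f_p)
    exp_r <- as.numeric(gm$signature %*% f_r) * de_mult
    if (patient_id[i] %in% cnv_pairs) {
      exp_r[gm$gene_ids %in% gm$cnv_block] <-
        exp_r[gm$gene_ids %in% gm$cnv_block] * cfg$cnv_block_effect
    }
    lib_p <- runif(1, cfg$libsize_range[1], cfg$libsize_range[2])
    lib_r <- runif(1, cfg$libsize_range[1], cfg$libsize_range[2])
    counts[, 2 * i - 1] <- sample_counts(exp_p, lib_p, cfg$nb_dispersion)
    counts[, 2 * i] <- sample_counts(exp_r, lib_r, cfg$nb_dispersion)
    relapse_score[i] <- if (length(up_genes)) {
      mean(log2(exp_r[gm$gene_ids %in% up_genes] + 1))
    } else 0
  }

  # survival: exponential PH model, linear predictor = loghr * z(score)
  z <- if (sd(relapse_score) > 0) as.numeric(scale(relapse_score)) else rep(0, n_pat)
  lp <- cfg$survival_metagene_loghr * z
  os_t <- rexp(n_pat, rate = exp(lp) / cfg$survival_baseline_scale)
  pfs_t <- rexp(n_pat, rate = exp(lp) / (cfg$survival_baseline_scale / 2))
  censored_os <- runif(n_pat) < cfg$censor_rate
  censored_pfs <- runif(n_pat) < cfg$censor_rate
  os_months <- ifelse(censored_os, runif(n_pat) * os_t, os_t)
  pfs_months <- ifelse(censored_pfs, runif(n_pat) * pfs_t, pfs_t)

  annotation <- tibble::tibble(
    sample_id = sample_id,
    patient_id = rep(patient_id, each = 2),
    timepoint = rep(c("primary", "relapse"), n_pat),
    group = rep(groups, each = 2),
    subgroup = rep(subgroup, each = 2),
    age_years = rep(round(age, 1), each = 2),
    sex = rep(sex, each = 2),
    relapse_pattern = rep(relapse_pattern, each = 2),
    m_stage = rep(m_stage, each = 2),
    novel_cnv = rep(novel_cnv, each = 2),
    pfs_months = rep(round(pfs_months, 2), each = 2),
    os_months = rep(round(os_months, 2), each = 2),
    os_event = rep(as.integer(!censored_os), each = 2),
    pfs_event = rep(as.integer(!censored_pfs), each = 2)
  )

  # SNP fingerprints shared within patients
  maf <- runif(cfg$n_snp_sites, 0.15, 0.5)
  genotypes <- vapply(seq_len(n_pat),
                      function(i) rbinom(cfg$n_snp_sites, 2, maf),
                      integer(cfg$n_snp_sites))
  dimnames(genotypes) <- list(sprintf("s%04d", seq_len(cfg$n_snp_sites)), patient_id)
  vaf <- matrix(NA_real_, cfg$n_snp_sites, 2 * n_pat,
                dimnames = list(rownames(genotypes), sample_id))
  for (i in seq_len(n_pat)) {
    for (j in c(2 * i - 1, 2 * i)) {
      vaf[, j] <- pmin(1, pmax(0, genotypes[, i] / 2 +
                                 rnorm(cfg$n_snp_sites, 0, 0.04)))
    }
  }

  expected_ratio <- matrix(
    vapply(names(cfg$n_patients_per_group), function(g) {
      a_p <- cfg$dirichlet_alpha_primary[[g]]
      a_r <- cfg$dirichlet_alpha_relapse[[g]]
      (a_r / sum(a_r)) / (a_p / sum(a_p))
    }, numeric(k)),
    nrow = k, dimnames = list(cfg$cell_types, names(cfg$n_patients_per_group)))

  gene_info <- tibble::tibble(gene_id = gm$gene_ids, length_bp = gm$length_bp,
                              chrom = gm$chrom)
  truth <- list(
    true_fractions = fractions,
    true_de_genes = tibble::tibble(gene = gm$de_genes, sign = gm$de_sign,
                                   log2fc = gm$de_sign * cfg$de_log2fc),
    true_metagene_beta = cfg$survival_metagene_loghr,
    pair_assignments = tibble::tibble(patient_id = patient_id,
                                      primary = paste0(patient_id, "_P"),
                                      relapse = paste0(patient_id, "_R")),
    cnv_pairs = cnv_pairs,
    cnv_block = gm$cnv_block,
    snp_genotypes = genotypes,
    signature = gm$signature,
    marker_sets = gm$marker_sets,
    expected_fraction_ratio = expected_ratio
  )
  list(counts = expr_matrix(counts, "counts"), gene_info = gene_info,
       annotation = annotation, vaf = vaf, truth = truth)
}

#' Simulate a labeled single-cell reference
#'
#' Per-cell negative-binomial counts around the same cell-type signature
#' profiles used by [simulate_cohort()], at single-cell library sizes.
#'
#' @param config A [simulation_config()].
#' @return List with `sc_counts` (expression matrix, `counts` scale),
#'   `labels` (cell-type label per cell) and `signature` (generating
#'   genes x types profile).
#' @export
simulate_sc_reference <- function(config) {
  validate_config(config)
  gm <- make_gene_model(config)
  cfg <- config
  k <- length(cfg$cell_types)
  n_cells <- cfg$cells_per_type * k
  labels <- rep(cfg$cell_types, each = cfg$cells_per_type)
  counts <- matrix(0L, cfg$n_genes, n_cells,
                   dimnames = list(gm$gene_ids,
                                   sprintf("cell%05d", seq_len(n_cells))))
  for (j in seq_len(n_cells)) {
    lib <- runif(1, 2000, 10000)
    counts[, j] <- sample_counts(gm$signature[, labels[j]], lib, cfg$nb_dispersion)
  }
  list(sc_counts = expr_matrix(counts, "counts"), labels = labels,
       signature = gm$signature)
}

#' Write all cohort files to a directory
#'
#' Emits the counts, gene-info, annotation and VAF tables as TSV, the
#' generating truth as JSON, and (optionally) the single-cell reference.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param sc Optional output of [simulate_sc_reference()].
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort_files <- function(sim, dir, sc = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = write_expression(sim$counts, file.path(dir, "counts.tsv")),
    gene_info = write_gene_info(sim$gene_info, file.path(dir, "gene_info.tsv")),
    annotation = write_annotation(sim$annotation, file.path(dir, "annotation.tsv")),
    vaf = write_vaf(sim$vaf, file.path(dir, "vaf.tsv"))
  )
  truth <- sim$truth
  truth$true_fractions <- as.data.frame(truth$true_fractions)
  truth$snp_genotypes <- as.data.frame(truth$snp_genotypes)
  truth$signature <- as.data.frame(truth$signature)
  truth$expected_fraction_ratio <- as.data.frame(truth$expected_fraction_ratio)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       dataframe = "columns")
  paths <- c(paths, truth = file.path(dir, "truth.json"))
  if (!is.null(sc)) {
    paths <- c(paths,
               sc_counts = write_expression(sc$sc_counts, file.path(dir, "sc_counts.tsv")),
               sc_labels = write_tsv_commented(
                 tibble::tibble(cell_id = colnames(sc$sc_counts), label = sc$labels),
                 file.path(dir, "sc_labels.tsv")))
  }
  invisible(paths)
}
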