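# Shared fixtures: small, fast simulation configs and ad-hoc matrices.

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_patients_per_group = c(SHH = 8, G3 = 4, G4 = 6),
         n_genes = 600, n_de_genes = 40, n_snp_sites = 120,
         libsize_range = c(2e5, 5e5), cells_per_type = 40, seed = seed),
    list(...))
  do.call(simulation_config, args)
}

# two-group null config: identical primary/relapse composition, no DE genes,
# no CNV effect, no survival signal
null_config <- function(seed, n_per_group = 12, n_genes = 400) {
  alpha <- c(A1 = 6, A2 = 6, B1 = 7, B2 = 7, C1 = 7, C2 = 7)
  simulation_config(
    n_patients_per_group = c(X = n_per_group, Y = n_per_group),
    n_genes = n_genes,
    dirichlet_alpha_primary = list(X = alpha, Y = alpha),
    dirichlet_alpha_relapse = list(X = alpha, Y = alpha),
    n_de_genes = 0, cnv_pair_fraction = 0, survival_metagene_loghr = 0,
    libsize_range = c(2e5, 4e5), n_snp_sites = 60, cells_per_type = 30,
    seed = seed)
}

random_expr <- function(n_genes, n_samples, seed = 1, scale = "log2rpkm") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 5, sd = 2), n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  attr(m, "scale") <- scale
  m
}

random_counts <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = 50, size = 5), n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  expr_matrix(m, "counts")
}

toy_annotation <- function(n_pairs, groups = "SHH") {
  pid <- sprintf("P%03d", seq_len(n_pairs))
  tibble::tibble(
    sample_id = c(rbind(paste0(pid, "_P"), paste0(pid, "_R"))),
    patient_id = rep(pid, each = 2),
    timepoint = rep(c("primary", "relapse"), n_pairs),
    group = rep(rep_len(groups, n_pairs), each = 2))
}
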