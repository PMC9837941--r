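# One-config orchestration of the full study workflow:
# simulate -> normalize -> pair variance -> paired DGE -> deconvolution ->
# survival -> fingerprint, with a manifest of content-hashed outputs.

#' Build or load a pipeline configuration
#'
#' @param x Either a named list of settings or the path of a YAML file.
#'   Recognized fields: `out_dir`, `seed`, `stages` (named logical toggles:
#'   simulate, normalize, variance, dge, deconvolution, survival,
#'   fingerprint), `simulation` (arguments for [simulation_config()]),
#'   `analysis` (`n_hvg`, `n_pcs`, `dge_groups`, `alpha`, `top_k`,
#'   `markers_per_type`, `n_perm`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  defaults <- list(
    out_dir = tempfile("relapsedelta_run_"),
    seed = 1L,
    stages = list(simulate = TRUE, normalize = TRUE, variance = TRUE,
                  dge = TRUE, deconvolution = TRUE, survival = TRUE,
                  fingerprint = TRUE),
    simulation = list(),
    analysis = list(n_hvg = 500, n_pcs = 3, dge_groups = c("G3", "G4"),
                    alpha = 0.05, top_k = 20, markers_per_type = 50,
                    n_perm = 100)
  )
  cfg <- utils::modifyList(defaults, x)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, fun) {
  tryCatch(fun(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages run in dependency order; each written artifact is recorded in a
#' manifest with its MD5 content hash, so a rerun under the same seed can be
#' verified bit-identical. A stage failure halts the run naming the stage.
#'
#' @param config A [pipeline_config()] (or list/YAML path coerced to one).
#' @return Tibble manifest: `stage`, `file`, `md5`. Also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, paths) {
    paths <- unname(paths)
    manifest[[length(manifest) + 1]] <<-
      tibble::tibble(stage = stage, file = basename(paths),
                     md5 = unname(tools::md5sum(paths)))
  }
  st <- config$stages
  an <- config$analysis
  out <- config$out_dir
  sim <- sc <- NULL

  if (isTRUE(st$simulate)) {
    run_stage("simulate", function() {
      sim_cfg <- do.call(simulation_config,
                         utils::modifyList(list(seed = config$seed),
                                           config$simulation))
      sim <<- simulate_cohort(sim_cfg)
      sc <<- simulate_sc_reference(sim_cfg)
      note("simulate", write_cohort_files(sim, out, sc = sc))
    })
  }
  if (is.null(sim)) return(finish_manifest(manifest, out))

  lrpkm <- cpm <- NULL
  if (isTRUE(st$normalize)) {
    run_stage("normalize", function() {
      lrpkm <<- log2_rpkm(sim$counts, sim$gene_info)
      cpm <<- cpm_normalize(sim$counts)
      note("normalize", c(write_expression(lrpkm, file.path(out, "log2rpkm.tsv")),
                          write_expression(cpm, file.path(out, "cpm.tsv"))))
    })
  }
  if (is.null(lrpkm)) return(finish_manifest(manifest, out))

  if (isTRUE(st$variance)) {
    run_stage("variance", function() {
      pv <- pair_variance(lrpkm, sim$annotation, n_hvg = an$n_hvg,
                          n_pcs = an$n_pcs)
      groups <- sim$annotation[sim$annotation$timepoint == "primary",
                               c("patient_id", "group")]
      cmp <- compare_groups(pv$distances, groups)
      p1 <- write_tsv_commented(pv$distances, file.path(out, "pair_distances.tsv"))
      p2 <- write_tsv_commented(pv$scores, file.path(out, "pca_scores.tsv"))
      p3 <- write_tsv_commented(cmp, file.path(out, "variance_comparisons.tsv"))
      note("variance", c(p1, p2, p3))
    })
  }

  dge <- NULL
  if (isTRUE(st$dge)) {
    run_stage("dge", function() {
      dge <<- paired_dge(lrpkm, sim$annotation, groups = an$dge_groups,
                         alpha = an$alpha, top_k = an$top_k)
      note("dge", write_tsv_commented(dge$table, file.path(out, "dge_table.tsv")))
    })
  }

  if (isTRUE(st$deconvolution)) {
    run_stage("deconvolution", function() {
      sig <- build_signature(sc$sc_counts, sc$labels,
                             markers_per_type = an$markers_per_type)
      dec <- deconvolve_nnls(cpm, sig, n_perm = an$n_perm)
      pairs <- pair_index(sim$annotation)
      strata <- sim$annotation[sim$annotation$timepoint == "primary",
                               c("patient_id", "group")]
      names(strata)[2] <- "stratum"
      cmp <- compare_fractions(dec, pairs, strata)
      p1 <- write_tsv_commented(tidy(dec), file.path(out, "fractions.tsv"))
      p2 <- write_tsv_commented(cmp, file.path(out, "fraction_comparisons.tsv"))
      note("deconvolution", c(p1, p2))
    })
  }

  if (isTRUE(st$survival) && !is.null(dge)) {
    run_stage("survival", function() {
      rec <- survival_records(sim$annotation, "os")
      sample_of <- setNames(paste0(rec$patient_id, "_R"), rec$patient_id)
      scan_up <- kaplan_scan_genes(lrpkm, sample_of, rec$time, rec$event,
                                   dge$degs$top_up)
      scan_down <- kaplan_scan_genes(lrpkm, sample_of, rec$time, rec$event,
                                     dge$degs$top_down)
      mg <- build_metagene(scan_up, scan_down, alpha = an$alpha)
      paths <- c(write_tsv_commented(dplyr::bind_rows(scan_up, scan_down),
                                     file.path(out, "kaplan_scan.tsv")))
      if (length(mg$unfavorable) >= 1) {
        score <- metagene_score(lrpkm[, sample_of, drop = FALSE], mg$unfavorable)
        cox_dat <- data.frame(time = rec$time, event = rec$event,
                              metagene = as.numeric(scale(score)))
        cox <- cox_fit(cox_dat, "metagene")
        paths <- c(paths, write_tsv_commented(cox$table,
                                              file.path(out, "cox_metagene.tsv")))
      }
      note("survival", paths)
    })
  }

  if (isTRUE(st$fingerprint)) {
    run_stage("fingerprint", function() {
      fp <- fingerprint_check(sim$vaf, sim$annotation)
      note("fingerprint", write_tsv_commented(fp, file.path(out, "fingerprint.tsv")))
    })
  }

  finish_manifest(manifest, out)
}

finish_manifest <- function(manifest, out_dir) {
  m <- if (length(manifest)) dplyr::bind_rows(manifest) else {
    tibble::tibble(stage = character(), file = character(), md5 = character())
  }
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"), dataframe = "rows")
  m
}
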