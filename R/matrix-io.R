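#' @importFrom rlang .data
#' @importFrom stats var sd cor median quantile rnorm runif rbinom rnbinom rexp
#'   setNames complete.cases
#' @importFrom utils head
NULL

FILE_HEADER <- function() sprintf("#relapse-delta v%s", utils::packageVersion("relapsedelta"))

EXPR_SCALES <- c("counts", "log2rpkm", "cpm")

#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes as rows and
#' samples as columns, carrying a `scale` attribute that records the unit of
#' its entries: raw `counts`, `log2rpkm` (log2 reads per kilobase per million
#' with a pseudocount), or `cpm` (counts per million).
#'
#' @param values Numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids).
#' @param scale One of `"counts"`, `"log2rpkm"`, `"cpm"`.
#' @return The matrix with its `scale` attribute set.
#' @export
expr_matrix <- function(values, scale = c("counts", "log2rpkm", "cpm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop("expression matrix needs rownames (genes) and colnames (samples)", call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene id(s): ", paste(unique(gid[duplicated(gid)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample id(s): ", paste(unique(sid[duplicated(sid)]), collapse = ", "),
         call. = FALSE)
  }
  if (scale == "counts") {
    if (any(values < 0)) stop("counts must be non-negative", call. = FALSE)
    if (any(abs(values - round(values)) > 1e-8)) {
      stop("counts must be integral", call. = FALSE)
    }
  }
  attr(values, "scale") <- scale
  values
}

#' Scale tag of an expression matrix
#' @param mat Expression matrix.
#' @return Character scalar scale tag, or `NA` if unset.
#' @export
expr_scale <- function(mat) {
  s <- attr(mat, "scale")
  if (is.null(s)) NA_character_ else s
}

# -- expression matrices -------------------------------------------------

#' Read an expression matrix from TSV
#'
#' Expects a header row, gene ids in the first column, one column per sample.
#' Lines starting with `#` are ignored. Malformed numeric cells and duplicate
#' gene ids are rejected with the offending gene/sample named.
#'
#' @param path File path.
#' @param expected_scale Scale tag to attach (`"counts"`, `"log2rpkm"`, `"cpm"`).
#' @return Expression matrix (see [expr_matrix()]).
#' @export
read_expression <- function(path, expected_scale = "counts") {
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene id column plus >=1 sample", call. = FALSE)
  gid <- df[[1]]
  if (anyDuplicated(gid)) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
                 dimnames = list(gid, colnames(df)[-1]))
  for (j in seq_len(ncol(df) - 1L)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene %s, sample %s in %s",
                   col[bad[1]], gid[bad[1]], colnames(df)[j + 1L], path), call. = FALSE)
    }
    vals[, j] <- num
  }
  expr_matrix(vals, expected_scale)
}

#' Write an expression matrix to TSV
#' @param mat Expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(FILE_HEADER(), con)
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE,
                                                 digits = 15), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

# -- gene info ------------------------------------------------------------

#' Read a gene information table
#'
#' Three-column TSV: `gene_id`, `length_bp` (positive integer), `chrom`.
#' @param path File path.
#' @return Tibble with one row per gene.
#' @export
read_gene_info <- function(path) {
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(gene_id = "c", length_bp = "i", chrom = "c"),
                        progress = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in gene info", call. = FALSE)
  if (any(df$length_bp < 1L)) stop("gene lengths must be >= 1 bp", call. = FALSE)
  df
}

#' Write a gene information table
#' @param genes Tibble/data frame with `gene_id`, `length_bp`, `chrom`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_info <- function(genes, path) {
  write_tsv_commented(genes[, c("gene_id", "length_bp", "chrom")], path)
}

# -- cohort annotation ----------------------------------------------------

ANN_REQUIRED <- c("sample_id", "patient_id", "timepoint", "group")
TIMEPOINTS <- c("primary", "relapse")

#' Read a cohort annotation table
#'
#' One row per sample. Required columns: `sample_id`, `patient_id`,
#' `timepoint` (`primary`/`relapse`), `group`. Clinical columns
#' (`subgroup`, `age_years`, `sex`, `relapse_pattern`, `m_stage`, `novel_cnv`,
#' `pfs_months`, `os_months`, `os_event`, `pfs_event`) are kept when present;
#' missing values are the literal string `NA`.
#'
#' @param path File path.
#' @return Tibble, one row per sample.
#' @export
read_annotation <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                        na = "NA", progress = FALSE)
  missing <- setdiff(ANN_REQUIRED, colnames(df))
  if (length(missing)) {
    stop("annotation lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_tp <- setdiff(unique(df$timepoint), TIMEPOINTS)
  if (length(bad_tp)) {
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in annotation", call. = FALSE)
  for (col in intersect(c("age_years", "pfs_months", "os_months"), colnames(df))) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop("negative values in ", col, call. = FALSE)
    }
  }
  for (col in intersect(c("os_event", "pfs_event", "novel_cnv"), colnames(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' Write a cohort annotation table
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  write_tsv_commented(ann, path)
}

#' Index complete primary-relapse pairs
#'
#' Returns one row per patient that has exactly one primary and one relapse
#' sample, ordered by patient id. Patients with a duplicated timepoint raise
#' an error; incomplete patients are dropped with a warning.
#'
#' @param ann Annotation tibble (see [read_annotation()]).
#' @return Tibble with columns `patient_id`, `primary`, `relapse`.
#' @export
pair_index <- function(ann) {
  dup <- ann |>
    dplyr::count(.data$patient_id, .data$timepoint) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("patient(s) with duplicated timepoint: ",
         paste(unique(dup$patient_id), collapse = ", "), call. = FALSE)
  }
  wide <- ann |>
    dplyr::select("patient_id", "timepoint", "sample_id") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "sample_id")
  if (!"primary" %in% colnames(wide)) wide$primary <- NA_character_
  if (!"relapse" %in% colnames(wide)) wide$relapse <- NA_character_
  incomplete <- wide$patient_id[is.na(wide$primary) | is.na(wide$relapse)]
  if (length(incomplete)) {
    warning("dropping patient(s) without a complete pair: ",
            paste(incomplete, collapse = ", "), call. = FALSE)
  }
  wide |>
    dplyr::filter(!is.na(.data$primary), !is.na(.data$relapse)) |>
    dplyr::arrange(.data$patient_id) |>
    dplyr::select("patient_id", "primary", "relapse")
}

# -- gene sets ------------------------------------------------------------

#' Read a GMT gene set collection
#'
#' Broad-dialect GMT: tab-separated `name`, `description`, then member gene
#' ids. Set names must be unique and sets non-empty.
#'
#' @param path File path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene set names in GMT", call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- nm[lengths(sets) == 0L]
  if (length(empty)) stop("empty gene set(s): ", paste(empty, collapse = ", "), call. = FALSE)
  setNames(sets, nm)
}

#' Write a GMT gene set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(c(FILE_HEADER(), lines), path)
  invisible(path)
}

# -- VAF tables -----------------------------------------------------------

#' Read a variant-allele-fraction table
#'
#' Site-by-sample TSV of VAFs in \[0, 1\]; first column `site_id`.
#' @param path File path.
#' @return Numeric matrix, sites x samples.
#' @export
read_vaf <- function(path) {
  m <- read_expression(path, expected_scale = "cpm")
  attr(m, "scale") <- NULL
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop("VAF values must lie in [0, 1]", call. = FALSE)
  m
}

#' Write a variant-allele-fraction table
#' @param vaf Sites x samples numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vaf <- function(vaf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(FILE_HEADER(), con)
  writeLines(paste(c("site_id", colnames(vaf)), collapse = "\t"), con)
  body <- apply(vaf, 1, function(r) paste(r, collapse = "\t"))
  writeLines(paste(rownames(vaf), body, sep = "\t"), con)
  invisible(path)
}

# -- shared writer --------------------------------------------------------

write_tsv_commented <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(FILE_HEADER(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
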