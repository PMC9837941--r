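# SNV fingerprint identity checks: genotype calls from variant allele
# fractions and pairwise concordance, used to verify that both members of a
# primary-relapse pair really come from the same patient.

#' Genotype calls from variant allele fractions
#'
#' VAF strictly below `hom_ref_max` is called homozygous reference (0),
#' strictly above `hom_alt_min` homozygous alternate (2), anything between
#' (boundaries included) heterozygous (1). Missing VAFs stay `NA`.
#'
#' @param vaf Sites x samples VAF matrix in \[0, 1\].
#' @param hom_ref_max Upper VAF bound for a hom-ref call (default 0.1).
#' @param hom_alt_min Lower VAF bound for a hom-alt call (default 0.9).
#' @return Integer matrix of codes \{0, 1, 2, NA\}, same dimnames as `vaf`.
#' @export
genotype_calls <- function(vaf, hom_ref_max = 0.1, hom_alt_min = 0.9) {
  if (hom_ref_max >= hom_alt_min) stop("thresholds inverted", call. = FALSE)
  calls <- matrix(1L, nrow(vaf), ncol(vaf), dimnames = dimnames(vaf))
  calls[vaf < hom_ref_max] <- 0L
  calls[vaf > hom_alt_min] <- 2L
  calls[is.na(vaf)] <- NA_integer_
  calls
}

#' Genotype concordance between two samples
#'
#' Fraction of jointly called sites with identical genotype codes. A pair is
#' a `match` when the fraction reaches `match_threshold`; with fewer than
#' `min_sites` joint calls the verdict is `indeterminate`.
#'
#' @param calls Genotype code matrix from [genotype_calls()].
#' @param sample_a,sample_b Column names to compare.
#' @param min_sites Minimum jointly called sites (default 20).
#' @param match_threshold Concordance needed for a match verdict (default 0.8).
#' @return Tibble: `sample_a`, `sample_b`, `concordance`, `n_sites`, `verdict`.
#' @export
pair_concordance <- function(calls, sample_a, sample_b, min_sites = 20,
                             match_threshold = 0.8) {
  a <- calls[, sample_a]; b <- calls[, sample_b]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < min_sites) {
    return(tibble::tibble(sample_a = sample_a, sample_b = sample_b,
                          concordance = NA_real_, n_sites = n,
                          verdict = "indeterminate"))
  }
  conc <- mean(a[ok] == b[ok])
  tibble::tibble(sample_a = sample_a, sample_b = sample_b,
                 concordance = conc, n_sites = n,
                 verdict = ifelse(conc >= match_threshold, "match", "mismatch"))
}

#' Fingerprint check of all annotated primary-relapse pairs
#'
#' @param vaf Sites x samples VAF matrix.
#' @param ann Cohort annotation.
#' @param ... Passed to [genotype_calls()] / [pair_concordance()].
#' @param hom_ref_max,hom_alt_min See [genotype_calls()].
#' @return Tibble, one row per pair, with `patient_id` and the
#'   [pair_concordance()] columns.
#' @export
fingerprint_check <- function(vaf, ann, hom_ref_max = 0.1, hom_alt_min = 0.9, ...) {
  calls <- genotype_calls(vaf, hom_ref_max, hom_alt_min)
  pairs <- pair_index(ann)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    dplyr::bind_cols(tibble::tibble(patient_id = pairs$patient_id[i]),
                     pair_concordance(calls, pairs$primary[i], pairs$relapse[i], ...))
  })
}
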