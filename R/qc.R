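## SNP- and individual-level genotype quality control.
## Filter order follows routine practice for joint multi-population panels:
## per-population MAF filter, then per-population SNP call-rate filter
## (surviving panel = intersection across populations), then individual
## call rate, then imputation of the remaining missing calls.

snp_maf <- function(calls) {
  p <- colMeans(calls, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter SNPs on minor allele frequency and call rate
#'
#' Removes SNPs with MAF below `maf_min` (strict less-than; MAF computed on
#' non-missing calls) and then, among the survivors, SNPs with call rate
#' below `snp_call_min` (strict). With `per_population = TRUE` (the default)
#' both rules are applied within each population and a SNP is kept only if it
#' passes in every population, so the surviving panel is the intersection —
#' the joint relationship matrix needs one common panel. A SNP with no calls
#' at all is treated as call rate 0 and removed at the call-rate stage.
#'
#' @param genotypes a [genotype_matrix()] object.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param snp_call_min minimum SNP call rate (default 0.90).
#' @param per_population apply the rules within each population (default) or
#'   pooled across all individuals.
#' @return List with `genotypes` (filtered) and `report` (a `qc_report`).
#' @export
filter_snps <- function(genotypes, maf_min = 0.01, snp_call_min = 0.90,
                        per_population = TRUE) {
  calls <- genotypes$calls
  groups <- if (per_population) split(seq_len(nrow(calls)), genotypes$pop)
            else list(all = seq_len(nrow(calls)))
  pass_maf <- rep(TRUE, ncol(calls))
  for (idx in groups) {
    maf <- snp_maf(calls[idx, , drop = FALSE])
    ## NaN (no calls in this group) passes here; the call-rate stage removes it
    pass_maf <- pass_maf & (is.nan(maf) | maf >= maf_min)
  }
  n_removed_maf <- sum(!pass_maf)
  pass_cr <- rep(TRUE, ncol(calls))
  for (idx in groups) {
    cr <- colMeans(!is.na(calls[idx, , drop = FALSE]))
    pass_cr <- pass_cr & cr >= snp_call_min
  }
  keep <- pass_maf & pass_cr
  n_removed_cr <- sum(pass_maf & !pass_cr)
  if (!any(keep)) warning("no SNPs survive quality control")
  out <- genotype_matrix(calls[, keep, drop = FALSE], genotypes$pop,
                         genotypes$birth_date)
  report <- qc_report(n_snps_in = ncol(calls), n_removed_maf = n_removed_maf,
                      n_removed_snp_callrate = n_removed_cr,
                      n_snps_out = sum(keep), n_ind_in = nrow(calls),
                      n_ind_out = nrow(calls))
  list(genotypes = out, report = report)
}

#' Filter individuals on genotype call rate
#'
#' Removes individuals whose fraction of non-missing calls is below
#' `ind_call_min` (strict less-than). Intended to run after the SNP filters.
#'
#' @param genotypes a [genotype_matrix()] object.
#' @param ind_call_min minimum individual call rate (default 0.90).
#' @return List with `genotypes` and `report`.
#' @export
filter_individuals <- function(genotypes, ind_call_min = 0.90) {
  calls <- genotypes$calls
  cr <- rowMeans(!is.na(calls))
  keep <- cr >= ind_call_min
  if (!any(keep))
    stop(sprintf("all individuals fall below the call-rate threshold %.2f",
                 ind_call_min))
  out <- genotype_matrix(calls[keep, , drop = FALSE], genotypes$pop[keep],
                         if (is.null(genotypes$birth_date)) NULL
                         else genotypes$birth_date[keep])
  report <- qc_report(n_snps_in = ncol(calls), n_removed_maf = 0L,
                      n_removed_snp_callrate = 0L, n_snps_out = ncol(calls),
                      n_ind_in = nrow(calls), n_ind_out = sum(keep),
                      n_ind_removed_callrate = sum(!keep))
  list(genotypes = out, report = report)
}

#' Impute remaining missing genotype calls
#'
#' Simple allele-frequency imputation on the QC'd panel: `mean_round` fills a
#' missing call with `round(2 * p_hat)` for the SNP's observed (pooled) allele
#' frequency; `frequency_draw` samples a genotype from Hardy-Weinberg
#' proportions at `p_hat` using `seed`.
#'
#' @param genotypes a [genotype_matrix()] object.
#' @param mode `"mean_round"` (deterministic) or `"frequency_draw"`.
#' @param seed integer seed used by `frequency_draw`.
#' @return A [genotype_matrix()] with no missing calls, plus attribute
#'   `n_imputed_cells`.
#' @export
impute_missing <- function(genotypes, mode = c("mean_round", "frequency_draw"),
                           seed = 1L) {
  mode <- match.arg(mode)
  calls <- genotypes$calls
  miss <- is.na(calls)
  n_missing <- sum(miss)
  if (n_missing > 0) {
    p <- colMeans(calls, na.rm = TRUE) / 2
    if (anyNA(p) || any(is.nan(p)))
      stop("SNPs with no observed calls cannot be imputed; run filter_snps first")
    if (mode == "mean_round") {
      fill <- pmin(pmax(round(2 * p), 0), 2)
      for (j in which(colSums(miss) > 0))
        calls[miss[, j], j] <- fill[j]
    } else {
      set.seed(seed)
      for (j in which(colSums(miss) > 0)) {
        k <- sum(miss[, j])
        calls[miss[, j], j] <- stats::rbinom(k, 2L, p[j])
      }
    }
  }
  out <- genotype_matrix(calls, genotypes$pop, genotypes$birth_date)
  attr(out, "n_imputed_cells") <- n_missing
  out
}

#' Run the full genotype quality-control stage
#'
#' SNP MAF and call-rate filters, individual call-rate filter, then
#' imputation, with a merged report.
#'
#' @inheritParams filter_snps
#' @inheritParams filter_individuals
#' @param impute imputation mode passed to [impute_missing()].
#' @param seed seed for `frequency_draw` imputation.
#' @return List with `genotypes` (clean, no missing calls) and `report`.
#' @export
qc_genotypes <- function(genotypes, maf_min = 0.01, snp_call_min = 0.90,
                         ind_call_min = 0.90, per_population = TRUE,
                         impute = c("mean_round", "frequency_draw"),
                         seed = 1L) {
  s1 <- filter_snps(genotypes, maf_min, snp_call_min, per_population)
  s2 <- filter_individuals(s1$genotypes, ind_call_min)
  clean <- impute_missing(s2$genotypes, match.arg(impute), seed)
  report <- qc_report(n_snps_in = s1$report$n_snps_in,
                      n_removed_maf = s1$report$n_removed_maf,
                      n_removed_snp_callrate = s1$report$n_removed_snp_callrate,
                      n_snps_out = s1$report$n_snps_out,
                      n_ind_in = s2$report$n_ind_in,
                      n_ind_out = s2$report$n_ind_out,
                      n_ind_removed_callrate = s2$report$n_ind_removed_callrate,
                      n_imputed_cells = attr(clean, "n_imputed_cells"))
  list(genotypes = clean, report = report)
}

qc_report <- function(n_snps_in, n_removed_maf, n_removed_snp_callrate,
                      n_snps_out, n_ind_in, n_ind_out,
                      n_ind_removed_callrate = 0L, n_imputed_cells = 0L) {
  rep <- list(n_snps_in = n_snps_in, n_removed_maf = n_removed_maf,
              n_removed_snp_callrate = n_removed_snp_callrate,
              n_snps_out = n_snps_out, n_ind_in = n_ind_in,
              n_ind_out = n_ind_out,
              n_ind_removed_callrate = n_ind_removed_callrate,
              n_imputed_cells = n_imputed_cells)
  stopifnot(rep$n_snps_out ==
              rep$n_snps_in - rep$n_removed_maf - rep$n_removed_snp_callrate,
            all(unlist(rep) >= 0))
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  SNPs: %d in, %d removed (MAF), %d removed (call rate), %d out\n",
              x$n_snps_in, x$n_removed_maf, x$n_removed_snp_callrate,
              x$n_snps_out))
  cat(sprintf("  Individuals: %d in, %d removed (call rate), %d out\n",
              x$n_ind_in, x$n_ind_removed_callrate, x$n_ind_out))
  cat(sprintf("  Imputed cells: %d\n", x$n_imputed_cells))
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) as.data.frame(unclass(x))
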