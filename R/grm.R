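## VanRaden method-1 genomic relationship matrix and relationship summaries.

#' Observed allele frequencies of a clean genotype matrix
#'
#' Frequencies of the counted allele, `p_j = sum(calls_j) / (2n)`, pooled over
#' all genotyped individuals in the analysis. Requires a fully imputed matrix
#' and rejects monomorphic SNPs, which carry no relationship information and
#' make the VanRaden scaling degenerate.
#'
#' @param genotypes a [genotype_matrix()] or a plain 0/1/2 matrix.
#' @return Named numeric vector of per-SNP allele frequencies in (0, 1).
#' @export
allele_frequencies <- function(genotypes) {
  calls <- if (inherits(genotypes, "genotypes")) genotypes$calls else genotypes
  if (anyNA(calls))
    stop("missing genotype calls present; impute before computing frequencies")
  p <- colMeans(calls) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNPs present (allele frequency 0 or 1); ",
         "remove them with filter_snps before building the GRM")
  p
}

#' VanRaden method-1 genomic relationship matrix
#'
#' `G = M M' / (2 * sum_j p_j (1 - p_j))` with `M` the genotype matrix whose
#' column `j` is centered by `2 p_j`. A small ridge `epsilon * I` is added to
#' the diagonal so the matrix is safely invertible in the mixed-model
#' equations (no pedigree matrix exists here to blend with). With frequencies
#' computed from the same matrix, each row of the unregularized G sums to
#' zero (centering identity).
#'
#' @param genotypes a [genotype_matrix()] or plain 0/1/2 matrix with no
#'   missing calls.
#' @param freqs per-SNP allele frequencies used for centering; computed from
#'   `genotypes` via [allele_frequencies()] when `NULL`.
#' @param epsilon ridge added to the diagonal (default `1e-6`).
#' @return An object of class `grm`: list with `mat` (n x n symmetric, id
#'   dimnames), `ids`, `freqs`, `epsilon`.
#' @export
vanraden_grm <- function(genotypes, freqs = NULL, epsilon = 1e-6) {
  calls <- if (inherits(genotypes, "genotypes")) genotypes$calls else genotypes
  if (anyNA(calls)) stop("missing genotype calls present; impute first")
  if (is.null(freqs)) freqs <- allele_frequencies(calls)
  if (length(freqs) != ncol(calls))
    stop("length of freqs does not match the number of SNPs")
  if (any(freqs <= 0 | freqs >= 1))
    stop("allele frequencies must lie strictly in (0, 1)")
  M <- sweep(calls, 2L, 2 * freqs)
  denom <- 2 * sum(freqs * (1 - freqs))
  G <- tcrossprod(M) / denom
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + epsilon
  dimnames(G) <- list(rownames(calls), rownames(calls))
  structure(list(mat = G, ids = rownames(calls), freqs = freqs,
                 epsilon = epsilon),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix (VanRaden method 1): %d individuals\n",
              length(x$ids)))
  cat(sprintf("  mean diagonal %.3f, ridge epsilon %g\n",
              mean(diag(x$mat)) - x$epsilon, x$epsilon))
  invisible(x)
}

#' Within- and between-group relationship summary
#'
#' Mean and standard deviation of the off-diagonal genomic relationships
#' within each population and between populations, the statistic used to show
#' that two populations are genetically linked but diverged (between-mean
#' below the within-means).
#'
#' @param grm a [vanraden_grm()] object.
#' @param labels group label per individual, in GRM id order or named by id.
#' @return data.frame with columns `group1`, `group2`, `type`
#'   (within/between), `mean`, `sd`, `n_pairs`. A group of size 1 has an
#'   undefined within-mean (`NA`).
#' @export
relationship_summary <- function(grm, labels) {
  ids <- grm$ids
  if (!is.null(names(labels))) {
    if (!all(ids %in% names(labels))) stop("labels must cover all GRM ids")
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels must cover all GRM ids")
  }
  labels <- as.character(labels)
  gs <- sort(unique(labels))
  G <- grm$mat
  diag(G) <- NA  # off-diagonal entries only
  out <- list()
  for (i in seq_along(gs)) for (j in i:length(gs)) {
    block <- G[labels == gs[i], labels == gs[j], drop = FALSE]
    vals <- block[!is.na(block)]
    out[[length(out) + 1L]] <- data.frame(
      group1 = gs[i], group2 = gs[j],
      type = if (i == j) "within" else "between",
      mean = if (length(vals)) mean(vals) else NA_real_,
      sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
      n_pairs = if (i == j) length(vals) / 2 else length(vals),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a GRM as a TSV square matrix with a JSON metadata sidecar
#' @param grm a [vanraden_grm()] object.
#' @param path output TSV path; metadata written to `<path>.meta.json`.
#' @return Invisibly, `path`.
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(id = grm$ids, grm$mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(epsilon = grm$epsilon,
                            freq_source = "observed, pooled over all genotyped individuals",
                            freqs = grm$freqs),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GRM written by [write_grm()]
#' @param path TSV path.
#' @return A `grm` object (freqs and epsilon restored from the sidecar when
#'   present).
#' @export
read_grm <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df$id)
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- list(ids, ids)
  meta_path <- paste0(path, ".meta.json")
  eps <- 0; fr <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    eps <- meta$epsilon
    fr <- meta$freqs
  }
  structure(list(mat = mat, ids = ids, freqs = fr, epsilon = eps),
            class = "grm")
}
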