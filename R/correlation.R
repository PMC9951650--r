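#' Between-population genetic correlation from bivariate variance components
#'
#' `r_g = cov_g12 / sqrt(sigma2_g1 * sigma2_g2)`, the genetic correlation
#' between the same trait expressed in two populations/environments. When a
#' parameter covariance matrix is available (the inverse average-information
#' matrix of the REML fit), a delta-method standard error is attached.
#'
#' @param x either a bivariate [gblup()] fit / `gblup_vc` object, or the
#'   additive genetic variance of trait 1 (population 1).
#' @param ... passed to methods.
#' @return A list of class `genetic_correlation` with elements `rg` and `se`
#'   (`NA` when no parameter covariance is available).
#' @examples
#' ## milk yield worked example: printed bivariate components
#' genetic_correlation(470936.770, 102.627, 5005.297)$rg  # 0.720
#' @export
genetic_correlation <- function(x, ...) UseMethod("genetic_correlation")

#' @rdname genetic_correlation
#' @param sigma2_g2 additive genetic variance of trait 2 (population 2).
#' @param cov_g12 genetic covariance between the two traits.
#' @param vcov optional 3x3 covariance matrix of
#'   `(sigma2_g1, cov_g12, sigma2_g2)` for the delta-method SE.
#' @export
genetic_correlation.default <- function(x, sigma2_g2, cov_g12, vcov = NULL,
                                        ...) {
  sigma2_g1 <- x
  if (sigma2_g1 <= 0 || sigma2_g2 <= 0)
    stop("genetic variances must be strictly positive")
  rg <- cov_g12 / sqrt(sigma2_g1 * sigma2_g2)
  se <- NA_real_
  if (!is.null(vcov)) {
    ## gradient of rg w.r.t. (sigma2_g1, cov_g12, sigma2_g2)
    grad <- c(-rg / (2 * sigma2_g1), 1 / sqrt(sigma2_g1 * sigma2_g2),
              -rg / (2 * sigma2_g2))
    v <- drop(crossprod(grad, vcov %*% grad))
    if (is.finite(v) && v >= 0) se <- sqrt(v)
  }
  structure(list(rg = rg, se = se), class = "genetic_correlation")
}

#' @rdname genetic_correlation
#' @export
genetic_correlation.gblup_vc <- function(x, ...) {
  if (x$kind != "bivariate")
    stop("genetic correlation requires a bivariate fit")
  vcm <- NULL
  if (!is.null(x$ai_inverse)) {
    gn <- c("sigma2_g1", "cov_g12", "sigma2_g2")
    if (all(gn %in% rownames(x$ai_inverse)))
      vcm <- x$ai_inverse[gn, gn]
  }
  genetic_correlation.default(x$G0[1, 1], x$G0[2, 2], x$G0[1, 2], vcov = vcm)
}

#' @rdname genetic_correlation
#' @export
genetic_correlation.gblup <- function(x, ...) genetic_correlation(x$vc, ...)

#' @export
print.genetic_correlation <- function(x, ...) {
  if (is.na(x$se)) cat(sprintf("Genetic correlation r_g = %.3f\n", x$rg))
  else cat(sprintf("Genetic correlation r_g = %.3f (SE %.3f)\n", x$rg, x$se))
  invisible(x)
}

#' Classify genotype-by-environment interaction by Robertson's criterion
#'
#' A genetic correlation below 0.80 (strict) between the same trait in two
#' environments indicates genotype-by-environment interaction; at or above
#' the threshold the two expressions can be treated as one trait.
#'
#' @param rg genetic correlation(s) in \[-1, 1\].
#' @param threshold classification threshold (default 0.80).
#' @return Character vector: `"gxe_present"` or `"gxe_negligible"`.
#' @examples
#' classify_gxe(c(0.72, 0.80, 0.98))
#' @export
classify_gxe <- function(rg, threshold = 0.80) {
  if (any(rg < -1 | rg > 1)) stop("rg must lie in [-1, 1]")
  ifelse(rg < threshold, "gxe_present", "gxe_negligible")
}
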