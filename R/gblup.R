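#' Residual weights from DRP reliabilities
#'
#' The diagonal of the residual weight matrix `D` of the weighted GBLUP
#' models: `d_ii = (1 - r2_i) / r2_i` for a record with reliability `r2_i`.
#' A reliability of exactly 1 would give weight 0 and an unbounded residual
#' precision, so reliabilities must be capped at 0.999 upstream.
#'
#' @param reliability numeric vector of reliabilities in (0, 0.999].
#' @return Numeric vector of positive residual weights.
#' @export
drp_weights <- function(reliability) {
  if (any(reliability <= 0 | reliability > 0.999))
    stop("reliabilities must lie in (0, 0.999]")
  (1 - reliability) / reliability
}

#' Fit a weighted GBLUP model (single-trait or two-trait)
#'
#' Fits the genomic best linear unbiased prediction model
#' `y = 1 mu + Z g + e` with `g ~ N(0, G sigma2_g)` and
#' `e ~ N(0, D sigma2_e)`, where `y` are de-regressed proofs (DRP), `G` is a
#' genomic relationship matrix and `D = diag((1 - r2_i) / r2_i)` weights each
#' residual by its record's reliability. In the two-trait (`bivariate`) form
#' the same trait measured in the two populations is treated as two
#' genetically correlated traits: `[g1; g2] ~ N(0, G0 (x) G)` with `G0` the
#' 2x2 genetic (co)variance matrix, and each population has its own residual
#' variance by default (the populations express the trait on different DRP
#' scales; set `shared_residual = TRUE` for a single residual variance).
#'
#' Variance components are estimated by restricted maximum likelihood using
#' average-information updates with an EM fallback (every accepted step is
#' non-decreasing in the restricted likelihood), unless fixed components are
#' supplied via `vc`. All individuals present in the GRM receive a direct
#' genomic value (DGV), including those without records, which are predicted
#' through their genomic relationships.
#'
#' @param drp data.frame of DRP records with columns `id`, `drp`,
#'   `reliability` and (for the bivariate model) `pop`; at most one record
#'   per individual per trait.
#' @param grm a [vanraden_grm()] object covering every record's individual.
#' @param model `"single"` or `"bivariate"`.
#' @param vc optional fixed variance components: for `single` a list with
#'   `sigma2_g` and `sigma2_e`; for `bivariate` a list with `G0` (2x2) and
#'   `sigma2_e` (length 2, or 1 to share). When supplied, no REML is run.
#' @param shared_residual fit one residual variance across the two
#'   populations instead of one per population (bivariate only).
#' @param method `"ai"` (average-information with EM fallback, default) or
#'   `"em"` (pure EM-REML).
#' @param max_iter,tol REML iteration cap and relative-change convergence
#'   tolerance.
#' @param verbose print per-iteration REML progress.
#' @return An object of class `gblup` with components `mu` (overall mean per
#'   trait), `dgv` (matrix of DGV, individuals x traits), `vc` (class
#'   `gblup_vc`), `fitted`, `residuals`, `records`, `loglik`.
#' @seealso [genetic_correlation()], [predict.gblup()], [run_scenarios()]
#' @examples
#' study <- sim_study(sim_config(n_ind_pop1 = 60, n_ind_pop2 = 60,
#'                               n_snps = 200, seed = 7))
#' qc <- qc_genotypes(study$genotypes)
#' G <- vanraden_grm(qc$genotypes)
#' fit <- gblup(study$drp, G, model = "bivariate", tol = 1e-6)
#' genetic_correlation(fit)
#' @export
gblup <- function(drp, grm, model = c("single", "bivariate"), vc = NULL,
                  shared_residual = FALSE, method = c("ai", "em"),
                  max_iter = 200L, tol = 1e-8, verbose = FALSE) {
  model <- match.arg(model)
  method <- match.arg(method)
  stopifnot(inherits(grm, "grm"))
  spec <- build_spec(drp, grm, model)
  G <- grm$mat
  Ginv <- tryCatch(chol2inv(chol(G)), error = function(e)
    stop("GRM is not positive definite; increase regularization_epsilon"))

  if (is.null(vc)) {
    rf <- reml_fit(spec, G, Ginv, method = method, max_iter = max_iter,
                   tol = tol, shared_residual = shared_residual,
                   verbose = verbose)
    vc_obj <- make_vc(rf$theta, model, shared_residual, spec,
                      converged = rf$converged,
                      n_iterations = rf$n_iterations,
                      ai_inverse = rf$ai_inverse, loglik = rf$loglik,
                      loglik_trace = rf$loglik_trace,
                      n_em_steps = rf$n_em_steps)
  } else {
    vc_obj <- as_vc(vc, model, shared_residual, spec)
  }

  if (model == "single") {
    sol <- mme_single(spec, Ginv, vc_obj$sigma2_g, vc_obj$sigma2_e)
    mu <- stats::setNames(sol$mu, spec$trait_name)
    dgv <- matrix(sol$g, ncol = 1L,
                  dimnames = list(spec$ids, spec$trait_name))
    fitted <- mu + sol$g[spec$zi]
  } else {
    if (abs(vc_obj$G0[1, 2]) >= sqrt(vc_obj$G0[1, 1] * vc_obj$G0[2, 2]))
      stop("G0 is singular (|genetic correlation| >= 1)")
    sol <- mme_bivariate(spec, Ginv, vc_obj$G0, vc_obj$sigma2_e)
    mu <- stats::setNames(sol$mu, spec$traits)
    dgv <- cbind(sol$g1, sol$g2)
    dimnames(dgv) <- list(spec$ids, spec$traits)
    g_own <- ifelse(spec$ti == 1L, sol$g1[spec$zi], sol$g2[spec$zi])
    fitted <- mu[spec$ti] + g_own
  }
  ll <- reml_loglik(vc_theta(vc_obj), v_components(
    spec, G[spec$zi, spec$zi, drop = FALSE], vc_obj$shared_residual),
    spec, design_X(spec))

  structure(list(call = match.call(), model = model, vc = vc_obj, mu = mu,
                 dgv = dgv, ids = spec$ids,
                 traits = colnames(dgv), records = drp, grm = grm,
                 fitted = unname(fitted),
                 residuals = spec$y - unname(fitted),
                 n = spec$n, loglik = ll),
            class = "gblup")
}

make_vc <- function(theta, model, shared_residual, spec, converged = NA,
                    n_iterations = 0L, ai_inverse = NULL, loglik = NA_real_,
                    loglik_trace = NULL, n_em_steps = NA_integer_) {
  if (model == "single") {
    vc <- list(kind = "single", sigma2_g = unname(theta[1]),
               sigma2_e = unname(theta[2]))
  } else {
    G0 <- matrix(c(theta[1], theta[2], theta[2], theta[3]), 2L,
                 dimnames = list(spec$traits, spec$traits))
    se <- if (shared_residual) rep(unname(theta[4]), 2L) else unname(theta[4:5])
    vc <- list(kind = "bivariate", G0 = G0,
               sigma2_e = stats::setNames(se, spec$traits))
  }
  vc$shared_residual <- shared_residual
  vc$converged <- converged
  vc$n_iterations <- n_iterations
  vc$ai_inverse <- ai_inverse
  vc$loglik <- loglik
  vc$loglik_trace <- loglik_trace
  vc$n_em_steps <- n_em_steps
  class(vc) <- "gblup_vc"
  vc
}

vc_theta <- function(vc) {
  if (vc$kind == "single") c(vc$sigma2_g, vc$sigma2_e)
  else if (vc$shared_residual)
    c(vc$G0[1, 1], vc$G0[1, 2], vc$G0[2, 2], vc$sigma2_e[1])
  else c(vc$G0[1, 1], vc$G0[1, 2], vc$G0[2, 2], vc$sigma2_e)
}

as_vc <- function(vc, model, shared_residual, spec) {
  if (inherits(vc, "gblup_vc")) {
    stopifnot(vc$kind == model)
    return(vc)
  }
  if (model == "single") {
    stopifnot(all(c("sigma2_g", "sigma2_e") %in% names(vc)),
              vc$sigma2_g > 0, vc$sigma2_e > 0)
    make_vc(c(vc$sigma2_g, vc$sigma2_e), model, shared_residual, spec)
  } else {
    stopifnot(all(c("G0", "sigma2_e") %in% names(vc)))
    G0 <- vc$G0
    stopifnot(is.matrix(G0), all(dim(G0) == 2L), G0[1, 1] > 0, G0[2, 2] > 0)
    se <- if (length(vc$sigma2_e) == 1L) rep(vc$sigma2_e, 2L) else vc$sigma2_e
    stopifnot(all(se > 0))
    make_vc(c(G0[1, 1], G0[1, 2], G0[2, 2], se), model,
            length(unique(se)) == 1L && shared_residual, spec)
  }
}

#' @export
print.gblup_vc <- function(x, ...) {
  if (x$kind == "single") {
    cat(sprintf("Variance components (single-trait): sigma2_g = %.6g, sigma2_e = %.6g\n",
                x$sigma2_g, x$sigma2_e))
    h2 <- x$sigma2_g / (x$sigma2_g + x$sigma2_e)
    cat(sprintf("  sigma2_g / (sigma2_g + sigma2_e) = %.3f\n", h2))
  } else {
    cat("Variance components (two-trait):\n  G0 =\n")
    print(round(x$G0, 6))
    cat("  residual variances:",
        paste(sprintf("%s = %.6g", names(x$sigma2_e), x$sigma2_e),
              collapse = ", "), "\n")
    rg <- x$G0[1, 2] / sqrt(x$G0[1, 1] * x$G0[2, 2])
    cat(sprintf("  genetic correlation = %.3f\n", rg))
  }
  if (!is.na(x$converged))
    cat(sprintf("  REML: %s in %d iterations (logLik %.4f)\n",
                if (isTRUE(x$converged)) "converged" else "NOT converged",
                x$n_iterations, x$loglik))
  invisible(x)
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("Weighted GBLUP fit (%s-trait model)\n",
              if (x$model == "single") "single" else "two"))
  cat(sprintf("  %d records, %d genotyped individuals, trait(s): %s\n",
              x$n, nrow(x$dgv), paste(x$traits, collapse = ", ")))
  cat("  overall mean(s):",
      paste(sprintf("%s = %.4f", names(x$mu), x$mu), collapse = ", "), "\n")
  print(x$vc)
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  out <- list(model = object$model, vc = object$vc, mu = object$mu,
              n = object$n, n_ind = nrow(object$dgv),
              dgv_sd = apply(object$dgv, 2, stats::sd),
              loglik = object$loglik)
  if (object$model == "bivariate")
    out$genetic_correlation <- genetic_correlation(object)
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat(sprintf("Weighted GBLUP (%s): %d records, %d individuals\n",
              x$model, x$n, x$n_ind))
  print(x$vc)
  cat("  DGV standard deviation per trait:",
      paste(sprintf("%s = %.4f", names(x$dgv_sd), x$dgv_sd),
            collapse = ", "), "\n")
  if (!is.null(x$genetic_correlation)) print(x$genetic_correlation)
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$mu

#' @export
fitted.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, ...) object$residuals

#' @export
logLik.gblup <- function(object, ...) {
  npar <- if (object$model == "single") 2L
          else if (object$vc$shared_residual) 4L else 5L
  structure(object$loglik, df = npar, class = "logLik")
}

#' @export
vcov.gblup <- function(object, ...) object$vc$ai_inverse

#' Direct genomic values from a GBLUP fit
#'
#' Every individual in the GRM has a DGV for every trait, whether or not it
#' contributed a record (unphenotyped individuals are predicted through their
#' genomic relationships).
#'
#' @param object a [gblup()] fit.
#' @param ids individuals to return (default all).
#' @param trait trait/column name (default all).
#' @param ... unused.
#' @return Matrix of DGV (ids x traits), or a named vector when a single
#'   trait is selected.
#' @export
predict.gblup <- function(object, ids = NULL, trait = NULL, ...) {
  out <- object$dgv
  if (!is.null(ids)) {
    if (!all(ids %in% rownames(out)))
      stop("some requested ids are not in the fitted GRM")
    out <- out[ids, , drop = FALSE]
  }
  if (!is.null(trait)) {
    out <- out[, trait, drop = TRUE]
  }
  out
}

#' @export
plot.gblup <- function(x, ...) {
  rec <- x$records
  obs <- rec$drp
  fit <- x$fitted
  grp <- if (x$model == "bivariate") as.factor(rec$pop) else
    factor(rep("records", length(obs)))
  graphics::plot(fit, obs, col = as.integer(grp) + 1L, pch = 16,
                 xlab = "fitted (mu + DGV)", ylab = "observed DRP", ...)
  graphics::abline(0, 1, lty = 2)
  if (nlevels(grp) > 1)
    graphics::legend("topleft", legend = levels(grp), col = 2:3, pch = 16,
                     bty = "n")
  invisible(x)
}

#' Simulate response vectors from a fitted GBLUP model
#'
#' Draws new DRP vectors `y* = X mu + Z g* + e*` with `g*` from the fitted
#' genetic covariance (`G sigma2_g`, or `G0 (x) G`) and `e*` from the fitted
#' weighted residual distribution.
#'
#' @param object a [gblup()] fit.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with one column per simulation, rows aligned with
#'   `object$records`.
#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rec <- object$records
  n <- nrow(rec)
  w <- drp_weights(rec$reliability)
  ids <- rownames(object$dgv)
  zi <- match(rec$id, ids)
  q <- length(ids)
  Gchol <- chol(object$grm$mat)
  ## chol(G0 (x) G) = chol(G0) (x) chol(G) keeps the bivariate case cheap
  Lg <- if (object$model == "single") {
    sqrt(object$vc$sigma2_g) * Gchol
  } else {
    kronecker(chol(object$vc$G0), Gchol)
  }
  out <- matrix(NA_real_, n, nsim)
  for (s in seq_len(nsim)) {
    if (object$model == "single") {
      se <- object$vc$sigma2_e
      gstar <- drop(crossprod(Lg, stats::rnorm(q)))
      out[, s] <- object$mu[1] + gstar[zi] + stats::rnorm(n, 0, sqrt(w * se))
    } else {
      ti <- match(as.character(rec$pop), object$traits)
      se <- object$vc$sigma2_e[ti]
      gstar <- drop(crossprod(Lg, stats::rnorm(2L * q)))
      g_own <- ifelse(ti == 1L, gstar[zi], gstar[q + zi])
      out[, s] <- object$mu[ti] + g_own + stats::rnorm(n, 0, sqrt(w * se))
    }
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
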