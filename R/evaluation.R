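## Validation designs (forward cutoff-date split, replicated stratified
## cross-validation) and the headline statistics: accuracy
## acc = cor(DRP, DGV) / rbar and unbiasedness b = cov(DRP, DGV) / var(DGV).

#' Forward (cutoff-date) reference/validation split
#'
#' Per population, the youngest fraction `ratio` of phenotyped individuals
#' (by birth date, ties broken by id order) forms the validation set and the
#' remainder the reference set — older animals predict younger ones, as in
#' routine genetic evaluation. Each population gets its own cutoff date.
#'
#' @param drp DRP table (`id`, `pop`, ...) of phenotyped individuals.
#' @param genotypes a [genotype_matrix()] carrying birth dates.
#' @param ratio target validation fraction per population (default 0.2, the
#'   4:1 reference:validation split).
#' @return A `split_plan` list: `kind = "forward"`, `reference_ids`,
#'   `validation_ids`, `cutoff_dates`.
#' @export
forward_split <- function(drp, genotypes, ratio = 0.2) {
  if (is.null(genotypes$birth_date))
    stop("forward split requires birth dates")
  stopifnot(ratio > 0, ratio < 1)
  bd <- genotypes$birth_date
  if (!all(drp$id %in% names(bd)))
    stop("birth date missing for some phenotyped individuals")
  val <- character(0)
  cutoffs <- list()
  for (p in sort(unique(drp$pop))) {
    ids <- drp$id[drp$pop == p]
    dts <- bd[ids]
    if (length(unique(dts)) == 1L)
      warning(sprintf("all individuals in %s share one birth date; ",
                      p), "splitting by id order")
    ord <- order(dts, ids, decreasing = TRUE)  # youngest first, ties by id
    n_val <- max(1L, round(ratio * length(ids)))
    vids <- ids[ord[seq_len(n_val)]]
    val <- c(val, vids)
    cutoffs[[p]] <- min(dts[vids])
  }
  structure(list(kind = "forward",
                 reference_ids = setdiff(drp$id, val),
                 validation_ids = val,
                 cutoff_dates = cutoffs),
            class = "split_plan")
}

#' Replicated stratified k-fold cross-validation plans
#'
#' Individuals are randomly split into `k` folds within each population, so
#' fold sizes within a population differ by at most 1 and each fold has
#' nearly the same number of individuals from each population. Replicate `r`
#' uses seed `seed + r`, so the whole design is reproducible and replicates
#' differ.
#'
#' @param drp DRP table of phenotyped individuals.
#' @param k folds (default 5).
#' @param replicates number of replicates (default 10).
#' @param seed base integer seed.
#' @return List of `k * replicates` `split_plan` objects with elements
#'   `fold` and `replicate`.
#' @export
cv_plan <- function(drp, k = 5L, replicates = 10L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  pops <- sort(unique(drp$pop))
  for (p in pops)
    if (sum(drp$pop == p) < k)
      stop(sprintf("population %s has fewer phenotyped individuals than k", p))
  plans <- list()
  for (r in seq_len(replicates)) {
    set.seed(seed + r)
    fold_of <- character(0)
    fold_id <- integer(0)
    for (p in pops) {
      ids <- sample(drp$id[drp$pop == p])
      fold_of <- c(fold_of, ids)
      fold_id <- c(fold_id, rep_len(seq_len(k), length(ids)))
    }
    for (f in seq_len(k)) {
      vids <- fold_of[fold_id == f]
      plans[[length(plans) + 1L]] <- structure(
        list(kind = "cv", reference_ids = setdiff(drp$id, vids),
             validation_ids = vids, fold = f, replicate = r, seed = seed + r),
        class = "split_plan")
    }
  }
  plans
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan (%s): %d reference, %d validation\n", x$kind,
              length(x$reference_ids), length(x$validation_ids)))
  if (x$kind == "cv")
    cat(sprintf("  replicate %d, fold %d\n", x$replicate, x$fold))
  invisible(x)
}

#' Genomic prediction accuracy
#'
#' `acc = cor(DRP, DGV) / rbar` over the validation animals, where `rbar` is
#' the average accuracy of the DRP itself. With `rbar_mode = "mean_sqrt"`
#' (default) `rbar` is the mean of `sqrt(reliability_i)` — the literal
#' "averaged accuracy" — while `"sqrt_mean"` takes the square root of the
#' mean reliability. Since `acc` divides a correlation by `rbar`, values
#' above 1 are possible.
#'
#' @param drp_values DRP of the validation animals.
#' @param reliabilities their DRP reliabilities.
#' @param dgv_values their predicted DGV.
#' @param rbar_mode `"mean_sqrt"` or `"sqrt_mean"`.
#' @return List with `accuracy`, `correlation`, `r_bar`, `n`. `accuracy` is
#'   `NA` (with a warning) when either vector has zero variance.
#' @export
prediction_accuracy <- function(drp_values, reliabilities, dgv_values,
                                rbar_mode = c("mean_sqrt", "sqrt_mean")) {
  rbar_mode <- match.arg(rbar_mode)
  n <- length(drp_values)
  if (n < 3L) stop("at least 3 validation animals required")
  r_bar <- switch(rbar_mode,
                  mean_sqrt = mean(sqrt(reliabilities)),
                  sqrt_mean = sqrt(mean(reliabilities)))
  if (stats::var(drp_values) == 0 || stats::var(dgv_values) == 0) {
    warning("zero variance in DRP or DGV; accuracy undefined")
    return(list(accuracy = NA_real_, correlation = NA_real_, r_bar = r_bar,
                n = n))
  }
  r <- stats::cor(drp_values, dgv_values)
  list(accuracy = r / r_bar, correlation = r, r_bar = r_bar, n = n)
}

#' Prediction unbiasedness (dispersion bias)
#'
#' `b = cov(DRP, DGV) / var(DGV)`, the regression of DRP on DGV in the
#' validation set; 1 means dispersion-unbiased prediction, above 1 means the
#' DGV are under-dispersed. Sample covariance and variance share one
#' denominator, so the ratio is convention-free.
#'
#' @param drp_values,dgv_values DRP and DGV of the validation animals.
#' @return Numeric `b`; `NA` with a warning when `var(DGV) = 0`.
#' @export
prediction_unbiasedness <- function(drp_values, dgv_values) {
  if (length(drp_values) < 3L) stop("at least 3 validation animals required")
  v <- stats::var(dgv_values)
  if (v == 0) {
    warning("zero variance in DGV; unbiasedness undefined")
    return(NA_real_)
  }
  stats::cov(drp_values, dgv_values) / v
}

#' Run the own-, cross- and joint-reference prediction scenarios
#'
#' For every split plan: the *own* scenario fits a single-trait GBLUP on the
#' validation population's own reference records; *cross* fits a single-trait
#' GBLUP on the other population's reference records and reads the validation
#' animals' DGV off through the genomic relationships; *joint* fits the
#' two-trait GBLUP on both reference sets and takes each validation animal's
#' DGV on its own population's trait. Validation DRP are excluded from every
#' fit and variance components are re-estimated per split, so no information
#' leaks from validation to reference.
#'
#' @param drp DRP table (single trait).
#' @param grm a [vanraden_grm()] over all individuals (reference and
#'   validation).
#' @param split a `split_plan` or a list of them (e.g. from [cv_plan()]).
#' @param scenarios subset of `c("own", "cross", "joint")`.
#' @param rbar_mode passed to [prediction_accuracy()].
#' @param shared_residual,method,max_iter,tol passed to [gblup()].
#' @param verbose print progress per plan.
#' @return data.frame of class `evaluation_metrics`: one row per scenario x
#'   validation population x plan with accuracy, unbiasedness, `r_bar`,
#'   validation size, and the joint fit's estimated genetic correlation.
#' @export
run_scenarios <- function(drp, grm, split,
                          scenarios = c("own", "cross", "joint"),
                          rbar_mode = c("mean_sqrt", "sqrt_mean"),
                          shared_residual = FALSE, method = "ai",
                          max_iter = 200L, tol = 1e-8, verbose = FALSE) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  rbar_mode <- match.arg(rbar_mode)
  if (length(unique(drp$trait)) > 1L)
    stop("run_scenarios handles one trait at a time")
  plans <- if (inherits(split, "split_plan")) list(split) else split
  pops <- sort(unique(drp$pop))
  stopifnot(length(pops) == 2L)
  rows <- list()
  for (pl in plans) {
    stopifnot(length(intersect(pl$reference_ids, pl$validation_ids)) == 0L)
    ref <- drp[drp$id %in% pl$reference_ids, , drop = FALSE]
    val <- drp[drp$id %in% pl$validation_ids, , drop = FALSE]
    fits_single <- list()
    if (any(c("own", "cross") %in% scenarios)) {
      for (p in pops) {
        rp <- ref[ref$pop == p, , drop = FALSE]
        if (nrow(rp) < 2L) { warning("too few reference records in ", p); next }
        fits_single[[p]] <- gblup(rp, grm, model = "single", method = method,
                                  max_iter = max_iter, tol = tol)
      }
    }
    fit_joint <- NULL
    if ("joint" %in% scenarios)
      fit_joint <- gblup(ref, grm, model = "bivariate",
                         shared_residual = shared_residual, method = method,
                         max_iter = max_iter, tol = tol)
    rg_hat <- if (!is.null(fit_joint))
      genetic_correlation(fit_joint)$rg else NA_real_
    for (p in pops) {
      vp <- val[val$pop == p, , drop = FALSE]
      if (nrow(vp) < 3L) { warning("too few validation animals in ", p); next }
      other <- setdiff(pops, p)
      for (sc in scenarios) {
        dgv <- switch(sc,
          own = if (!is.null(fits_single[[p]]))
            predict(fits_single[[p]], ids = vp$id)[, 1] else NULL,
          cross = if (!is.null(fits_single[[other]]))
            predict(fits_single[[other]], ids = vp$id)[, 1] else NULL,
          joint = predict(fit_joint, ids = vp$id, trait = p))
        if (is.null(dgv)) next
        acc <- prediction_accuracy(vp$drp, vp$reliability, dgv, rbar_mode)
        b <- prediction_unbiasedness(vp$drp, dgv)
        rows[[length(rows) + 1L]] <- data.frame(
          trait = drp$trait[1], scenario = sc, validation_pop = p,
          fold = if (!is.null(pl$fold)) pl$fold else NA_integer_,
          replicate = if (!is.null(pl$replicate)) pl$replicate else NA_integer_,
          accuracy = acc$accuracy, correlation = acc$correlation,
          unbiasedness = b, r_bar = acc$r_bar, n_validation = acc$n,
          rg_estimate = if (sc == "joint") rg_hat else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    if (verbose) message("completed plan with ",
                         length(pl$validation_ids), " validation animals")
  }
  out <- do.call(rbind, rows)
  ## provenance for leakage audits: the records each fit was allowed to see
  attr(out, "reference_ids") <- lapply(plans, function(p) sort(p$reference_ids))
  class(out) <- c("evaluation_metrics", "data.frame")
  out
}

#' Summarize evaluation metrics across folds and replicates
#'
#' Mean and SD of accuracy and unbiasedness per trait x scenario x validation
#' population, the mean(+-SD) shape used to report replicated
#' cross-validation.
#'
#' @param metrics an `evaluation_metrics` data.frame from [run_scenarios()].
#' @return data.frame with `accuracy_mean`, `accuracy_sd`,
#'   `unbiasedness_mean`, `unbiasedness_sd`, `n_splits`.
#' @export
summarize_metrics <- function(metrics) {
  key <- interaction(metrics$trait, metrics$scenario,
                     metrics$validation_pop, drop = TRUE)
  parts <- split(as.data.frame(metrics), key)
  out <- do.call(rbind, lapply(parts, function(d) data.frame(
    trait = d$trait[1], scenario = d$scenario[1],
    validation_pop = d$validation_pop[1],
    accuracy_mean = mean(d$accuracy, na.rm = TRUE),
    accuracy_sd = stats::sd(d$accuracy),
    unbiasedness_mean = mean(d$unbiasedness, na.rm = TRUE),
    unbiasedness_sd = stats::sd(d$unbiasedness),
    n_splits = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$scenario, out$validation_pop), ]
}
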