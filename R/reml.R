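## Internal machinery: mixed-model equations (MME) for the weighted GBLUP
## models and restricted maximum likelihood by average-information (AI)
## updates with a true EM-REML fallback.
##
## Parameter vectors:
##   single trait:  theta = (sigma2_g, sigma2_e)
##   two traits:    theta = (sigma2_g1, cov_g12, sigma2_g2, sigma2_e1, sigma2_e2)
##                  (one shared residual variance when shared_residual = TRUE)
## The record-space covariance V(theta) is linear in theta, which is what the
## AI algorithm exploits; each parameter's dV/dtheta_i is stored as either a
## (block of a) dense matrix or a diagonal.

## ---- model spec -----------------------------------------------------------

build_spec <- function(drp, grm, model) {
  stopifnot(is.data.frame(drp),
            all(c("id", "drp", "reliability") %in% colnames(drp)))
  ids <- grm$ids
  if (!all(drp$id %in% ids))
    stop("every DRP record must map to an individual present in the GRM")
  w <- drp_weights(drp$reliability)
  spec <- list(kind = model, y = as.numeric(drp$drp),
               zi = match(drp$id, ids), w = w, q = length(ids), ids = ids,
               n = nrow(drp),
               trait_name = if ("trait" %in% colnames(drp))
                 as.character(drp$trait[1]) else "trait")
  if (model == "bivariate") {
    if (!"pop" %in% colnames(drp))
      stop("bivariate model requires a 'pop' column (trait per population)")
    traits <- sort(unique(as.character(drp$pop)))
    if (length(traits) != 2)
      stop("bivariate model requires records from exactly two populations")
    spec$ti <- match(as.character(drp$pop), traits)
    spec$traits <- traits
    dup <- paste(drp$id, spec$ti)
    if (anyDuplicated(dup))
      stop("at most one record per individual per trait is supported")
  }
  spec
}

## ---- V components ---------------------------------------------------------

## Each component c of V = sum_i theta_i * C_i is one of
##   list(type = "block", r, c, M)  : M in rows r x cols c (+ transpose if r != c)
##   list(type = "diag", d)         : diag(d)
v_components <- function(spec, K, shared_residual = FALSE) {
  if (spec$kind == "single") {
    list(sigma2_g = list(type = "block", r = seq_len(spec$n),
                         c = seq_len(spec$n), M = K),
         sigma2_e = list(type = "diag", d = spec$w))
  } else {
    i1 <- which(spec$ti == 1L); i2 <- which(spec$ti == 2L)
    comps <- list(
      sigma2_g1 = list(type = "block", r = i1, c = i1,
                       M = K[i1, i1, drop = FALSE]),
      cov_g12 = list(type = "block", r = i1, c = i2,
                     M = K[i1, i2, drop = FALSE]),
      sigma2_g2 = list(type = "block", r = i2, c = i2,
                       M = K[i2, i2, drop = FALSE]))
    if (shared_residual) {
      comps$sigma2_e <- list(type = "diag", d = spec$w)
    } else {
      d1 <- spec$w; d1[i2] <- 0
      d2 <- spec$w; d2[i1] <- 0
      comps$sigma2_e1 <- list(type = "diag", d = d1)
      comps$sigma2_e2 <- list(type = "diag", d = d2)
    }
    comps
  }
}

build_V <- function(theta, comps, n) {
  V <- matrix(0, n, n)
  for (i in seq_along(comps)) {
    cm <- comps[[i]]
    if (cm$type == "diag") {
      diag(V) <- diag(V) + theta[i] * cm$d
    } else if (identical(cm$r, cm$c)) {
      V[cm$r, cm$c] <- V[cm$r, cm$c] + theta[i] * cm$M
    } else {
      V[cm$r, cm$c] <- V[cm$r, cm$c] + theta[i] * cm$M
      V[cm$c, cm$r] <- V[cm$c, cm$r] + theta[i] * t(cm$M)
    }
  }
  V
}

comp_times_vec <- function(cm, v) {
  out <- numeric(length(v))
  if (cm$type == "diag") return(cm$d * v)
  if (identical(cm$r, cm$c)) {
    out[cm$r] <- cm$M %*% v[cm$c]
  } else {
    out[cm$r] <- cm$M %*% v[cm$c]
    out[cm$c] <- crossprod(cm$M, v[cm$r])
  }
  out
}

comp_trace_P <- function(cm, P) {
  if (cm$type == "diag") return(sum(diag(P) * cm$d))
  if (identical(cm$r, cm$c)) return(sum(P[cm$r, cm$c] * cm$M))
  2 * sum(P[cm$r, cm$c] * cm$M)
}

design_X <- function(spec) {
  if (spec$kind == "single") matrix(1, spec$n, 1L)
  else cbind(as.numeric(spec$ti == 1L), as.numeric(spec$ti == 2L))
}

## Restricted log-likelihood -0.5 (log|V| + log|X'V^-1 X| + y'Py); -Inf when
## V is not positive definite at theta.
reml_loglik <- function(theta, comps, spec, X) {
  V <- build_V(theta, comps, spec$n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv_y <- backsolve(ch, forwardsolve(t(ch), spec$y))
  Vinv_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtVX <- crossprod(X, Vinv_X)
  chX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chX)) return(-Inf)
  logdetX <- 2 * sum(log(diag(chX)))
  Xty <- crossprod(X, Vinv_y)
  yPy <- sum(spec$y * Vinv_y) - sum(Xty * solve(XtVX, Xty))
  -0.5 * (logdetV + logdetX + yPy)
}

## Gradient and average-information matrix at theta.
ai_quantities <- function(theta, comps, spec, X) {
  V <- build_V(theta, comps, spec$n)
  ch <- chol(V)
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  P <- Vinv - VinvX %*% solve(XtVX, t(VinvX))
  Py <- drop(P %*% spec$y)
  k <- length(comps)
  grad <- numeric(k)
  S <- matrix(0, spec$n, k)
  for (i in seq_len(k)) {
    s <- comp_times_vec(comps[[i]], Py)
    S[, i] <- s
    grad[i] <- -0.5 * (comp_trace_P(comps[[i]], P) - sum(Py * s))
  }
  PS <- P %*% S
  AI <- 0.5 * crossprod(S, PS)
  list(grad = grad, AI = AI, P = P, Py = Py)
}

## ---- mixed-model equations ------------------------------------------------

aggregate_by_individual <- function(vals, zi, q) {
  out <- numeric(q)
  agg <- rowsum(vals, zi)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

## Single-trait MME: unknowns (mu, g_1..g_q); R = diag(w) * sigma2_e.
mme_single <- function(spec, Ginv, sigma2_g, sigma2_e, want_inverse = FALSE) {
  rinv <- 1 / (spec$w * sigma2_e)
  q <- spec$q
  u <- aggregate_by_individual(rinv, spec$zi, q)
  v <- aggregate_by_individual(rinv * spec$y, spec$zi, q)
  C <- matrix(0, q + 1L, q + 1L)
  C[1, 1] <- sum(rinv)
  C[1, -1] <- u
  C[-1, 1] <- u
  C[-1, -1] <- Ginv / sigma2_g
  diag(C)[-1] <- diag(C)[-1] + u
  rhs <- c(sum(rinv * spec$y), v)
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular mixed-model equations; increase the GRM regularization_epsilon"))
  sol <- backsolve(ch, forwardsolve(t(ch), rhs))
  out <- list(mu = sol[1], g = sol[-1])
  if (want_inverse) out$Cinv <- chol2inv(ch)
  out
}

## Two-trait MME: unknowns (mu1, mu2, g_trait1 (q), g_trait2 (q));
## genetic precision G0^-1 (x) G^-1, residual diag(w) * sigma2_e[trait].
mme_bivariate <- function(spec, Ginv, G0, sigma2_e, want_inverse = FALSE) {
  if (length(sigma2_e) == 1L) sigma2_e <- rep(sigma2_e, 2L)
  rg <- G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2])
  if (!is.finite(rg) || abs(rg) >= 1)
    stop("G0 is singular (|genetic correlation| >= 1)")
  q <- spec$q
  rinv <- 1 / (spec$w * sigma2_e[spec$ti])
  i1 <- spec$ti == 1L; i2 <- spec$ti == 2L
  u1 <- aggregate_by_individual(rinv[i1], spec$zi[i1], q)
  u2 <- aggregate_by_individual(rinv[i2], spec$zi[i2], q)
  v1 <- aggregate_by_individual((rinv * spec$y)[i1], spec$zi[i1], q)
  v2 <- aggregate_by_individual((rinv * spec$y)[i2], spec$zi[i2], q)
  G0inv <- solve(G0)
  p <- 2L + 2L * q
  b1 <- 2L + seq_len(q)
  b2 <- 2L + q + seq_len(q)
  C <- matrix(0, p, p)
  C[1, 1] <- sum(rinv[i1]); C[2, 2] <- sum(rinv[i2])
  C[1, b1] <- u1; C[b1, 1] <- u1
  C[2, b2] <- u2; C[b2, 2] <- u2
  C[b1, b1] <- G0inv[1, 1] * Ginv
  C[b1, b2] <- G0inv[1, 2] * Ginv
  C[b2, b1] <- G0inv[2, 1] * Ginv
  C[b2, b2] <- G0inv[2, 2] * Ginv
  diag(C)[b1] <- diag(C)[b1] + u1
  diag(C)[b2] <- diag(C)[b2] + u2
  rhs <- c(sum((rinv * spec$y)[i1]), sum((rinv * spec$y)[i2]), v1, v2)
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular mixed-model equations; increase the GRM regularization_epsilon"))
  sol <- backsolve(ch, forwardsolve(t(ch), rhs))
  out <- list(mu = sol[1:2], g1 = sol[b1], g2 = sol[b2])
  if (want_inverse) out$Cinv <- chol2inv(ch)
  out
}

## ---- EM-REML steps (monotone in the restricted likelihood) ---------------

em_step_single <- function(theta, spec, Ginv) {
  sg <- theta[1]; se <- theta[2]
  fit <- mme_single(spec, Ginv, sg, se, want_inverse = TRUE)
  q <- spec$q
  Cgg <- fit$Cinv[-1, -1]
  sg_new <- (drop(crossprod(fit$g, Ginv %*% fit$g)) + sum(Ginv * Cgg)) / q
  ehat <- spec$y - fit$mu - fit$g[spec$zi]
  gidx <- 1L + spec$zi
  quad <- fit$Cinv[1, 1] + 2 * fit$Cinv[1, gidx] + diag(fit$Cinv)[gidx]
  se_new <- sum((ehat^2 + quad) / spec$w) / spec$n
  c(sg_new, se_new)
}

em_step_bivariate <- function(theta, spec, Ginv, shared_residual) {
  G0 <- matrix(c(theta[1], theta[2], theta[2], theta[3]), 2L)
  sigma2_e <- if (shared_residual) rep(theta[4], 2L) else theta[4:5]
  fit <- mme_bivariate(spec, Ginv, G0, sigma2_e, want_inverse = TRUE)
  q <- spec$q
  b <- list(2L + seq_len(q), 2L + q + seq_len(q))
  U <- cbind(fit$g1, fit$g2)
  TT <- matrix(0, 2L, 2L)
  for (k in 1:2) for (l in k:2) {
    TT[k, l] <- TT[l, k] <- sum(Ginv * fit$Cinv[b[[k]], b[[l]]])
  }
  G0_new <- (crossprod(U, Ginv %*% U) + TT) / q
  G0_new <- (G0_new + t(G0_new)) / 2
  ghat <- list(fit$g1, fit$g2)
  se_num <- numeric(2L); se_den <- numeric(2L)
  for (t in 1:2) {
    idx <- which(spec$ti == t)
    zi <- spec$zi[idx]
    ehat <- spec$y[idx] - fit$mu[t] - ghat[[t]][zi]
    gidx <- b[[t]][zi]
    quad <- fit$Cinv[t, t] + 2 * fit$Cinv[t, gidx] + diag(fit$Cinv)[gidx]
    se_num[t] <- sum((ehat^2 + quad) / spec$w[idx])
    se_den[t] <- length(idx)
  }
  if (shared_residual) {
    c(G0_new[1, 1], G0_new[1, 2], G0_new[2, 2], sum(se_num) / sum(se_den))
  } else {
    c(G0_new[1, 1], G0_new[1, 2], G0_new[2, 2], se_num / se_den)
  }
}

## ---- feasibility ----------------------------------------------------------

theta_feasible <- function(theta, spec, floors, shared_residual) {
  if (spec$kind == "single") {
    all(theta > floors)
  } else {
    vg1 <- theta[1]; c12 <- theta[2]; vg2 <- theta[3]
    res <- theta[-(1:3)]
    vg1 > floors[1] && vg2 > floors[3] && all(res > floors[-(1:3)]) &&
      abs(c12) <= 0.999 * sqrt(vg1 * vg2)
  }
}

clamp_theta <- function(theta, spec, floors, shared_residual, warn = TRUE) {
  if (spec$kind == "single") {
    pinned <- theta < floors
    theta <- pmax(theta, floors)
  } else {
    pinned <- c(theta[1] < floors[1], FALSE, theta[3] < floors[3],
                theta[-(1:3)] < floors[-(1:3)])
    theta[1] <- max(theta[1], floors[1])
    theta[3] <- max(theta[3], floors[3])
    theta[-(1:3)] <- pmax(theta[-(1:3)], floors[-(1:3)])
    cmax <- 0.999 * sqrt(theta[1] * theta[3])
    theta[2] <- min(max(theta[2], -cmax), cmax)
  }
  if (warn && any(pinned))
    warning("variance component pinned at its lower floor during REML")
  theta
}

## ---- driver ---------------------------------------------------------------

reml_fit <- function(spec, G, Ginv, init = NULL,
                     method = c("ai", "em"), max_iter = 200L, tol = 1e-8,
                     shared_residual = FALSE, verbose = FALSE) {
  method <- match.arg(method)
  if (spec$n < 2L || (spec$kind == "bivariate" &&
                      (sum(spec$ti == 1L) < 2L || sum(spec$ti == 2L) < 2L)))
    stop("REML needs at least 2 records per trait")
  K <- G[spec$zi, spec$zi, drop = FALSE]
  comps <- v_components(spec, K, shared_residual)
  X <- design_X(spec)
  pnames <- names(comps)

  if (spec$kind == "single") {
    vy <- stats::var(spec$y)
    floors <- rep(1e-8 * vy, 2L)
    if (is.null(init)) init <- c(vy / 2, vy / 2)
  } else {
    vy1 <- stats::var(spec$y[spec$ti == 1L])
    vy2 <- stats::var(spec$y[spec$ti == 2L])
    floors <- if (shared_residual)
      c(1e-8 * vy1, NA, 1e-8 * vy2, 1e-8 * min(vy1, vy2))
    else c(1e-8 * vy1, NA, 1e-8 * vy2, 1e-8 * vy1, 1e-8 * vy2)
    if (is.null(init)) {
      init <- if (shared_residual) c(vy1 / 2, 0, vy2 / 2, (vy1 + vy2) / 4)
              else c(vy1 / 2, 0, vy2 / 2, vy1 / 2, vy2 / 2)
    }
  }

  em_step <- function(th) {
    if (spec$kind == "single") em_step_single(th, spec, Ginv)
    else em_step_bivariate(th, spec, Ginv, shared_residual)
  }

  theta <- init
  ll <- reml_loglik(theta, comps, spec, X)
  ll_trace <- ll
  converged <- FALSE
  pinned_any <- FALSE
  n_em <- 0L
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    theta_new <- NULL
    used_em <- FALSE
    if (method == "ai" && it > 1L) {
      aiq <- ai_quantities(theta, comps, spec, X)
      delta <- tryCatch(solve(aiq$AI, aiq$grad), error = function(e) NULL)
      if (!is.null(delta)) {
        for (h in 0:4) {  # step-halving; proposals outside the parameter
          prop <- clamp_theta(theta + delta / 2^h, spec, floors,  # space are
                              shared_residual, warn = FALSE)  # pinned, not lost
          llp <- reml_loglik(prop, comps, spec, X)
          if (llp >= ll - 1e-10) {
            theta_new <- prop; ll_new <- llp; break
          }
        }
      }
    }
    if (is.null(theta_new)) {
      raw <- em_step(theta)
      theta_new <- clamp_theta(raw, spec, floors, shared_residual,
                               warn = FALSE)
      if (any(theta_new != raw)) pinned_any <- TRUE
      ll_new <- reml_loglik(theta_new, comps, spec, X)
      used_em <- TRUE
      n_em <- n_em + 1L
    }
    if (verbose)
      message(sprintf("iter %3d (%s)  logLik %.8f  theta: %s", it,
                      if (used_em) "EM" else "AI", ll_new,
                      paste(signif(theta_new, 6), collapse = " ")))
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-12))
    ll_trace <- c(ll_trace, ll_new)
    theta <- theta_new
    ll <- ll_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("REML did not converge in %d iterations", max_iter))
  if (pinned_any)
    warning("a variance component was pinned at its lower floor during REML")

  ai_inv <- NULL
  aiq <- tryCatch(ai_quantities(theta, comps, spec, X),
                  error = function(e) NULL)
  if (!is.null(aiq)) {
    ai_inv <- tryCatch(solve(aiq$AI), error = function(e) NULL)
    if (!is.null(ai_inv)) dimnames(ai_inv) <- list(pnames, pnames)
  }
  names(theta) <- pnames
  list(theta = theta, converged = converged, n_iterations = iterations,
       loglik = ll, loglik_trace = ll_trace, ai_inverse = ai_inv,
       n_em_steps = n_em)
}
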