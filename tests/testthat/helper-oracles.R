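## Independent oracles used across the test suite. These deliberately use
## naive dense / scalar-loop formulations, never the package's solvers.

## GLS/BLUP closed form for the single-trait weighted GBLUP:
## mu = (1'V^-1 1)^-1 1'V^-1 y,  g = sg * G[,zi] V^-1 (y - 1 mu),
## V = sg * G[zi,zi] + se * diag(w). Returns DGV for all individuals in G.
gls_oracle_single <- function(y, zi, w, G, sg, se) {
  V <- sg * G[zi, zi, drop = FALSE] + diag(w * se, length(y))
  Vinv <- solve(V)
  one <- rep(1, length(y))
  mu <- drop(crossprod(one, Vinv %*% y) / crossprod(one, Vinv %*% one))
  g <- drop(sg * G[, zi, drop = FALSE] %*% (Vinv %*% (y - mu)))
  list(mu = mu, g = unname(g))
}

## Dense GLS/BLUP oracle for the two-trait model built from the full
## covariance: V_rs = G0[t_r, t_s] G[i_r, i_s] + delta_rs w_r se[t_r],
## Cov(g_k[j], y_r) = G0[k, t_r] G[j, i_r].
gls_oracle_bivariate <- function(y, zi, ti, w, G, G0, se) {
  if (length(se) == 1L) se <- rep(se, 2L)
  n <- length(y)
  q <- nrow(G)
  V <- matrix(0, n, n)
  for (r in seq_len(n)) for (s in seq_len(n)) {
    V[r, s] <- G0[ti[r], ti[s]] * G[zi[r], zi[s]]
    if (r == s) V[r, s] <- V[r, s] + w[r] * se[ti[r]]
  }
  X <- cbind(as.numeric(ti == 1L), as.numeric(ti == 2L))
  Vinv <- solve(V)
  mu <- drop(solve(crossprod(X, Vinv %*% X), crossprod(X, Vinv %*% y)))
  Cgy <- matrix(0, 2L * q, n)
  for (k in 1:2) for (j in seq_len(q)) for (r in seq_len(n))
    Cgy[(k - 1L) * q + j, r] <- G0[k, ti[r]] * G[j, zi[r]]
  g <- drop(Cgy %*% (Vinv %*% (y - X %*% mu)))
  list(mu = mu, g1 = g[seq_len(q)], g2 = g[q + seq_len(q)])
}

## Restricted log-likelihood evaluated from first principles (dense V,
## determinant()), independent of the package's chol-based version.
reml_loglik_oracle <- function(sg, se, y, zi, w, G) {
  V <- sg * G[zi, zi, drop = FALSE] + diag(w * se, length(y))
  X <- matrix(1, length(y), 1L)
  ld <- determinant(V, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  Vinv <- solve(V)
  XtVX <- crossprod(X, Vinv %*% X)
  P <- Vinv - Vinv %*% X %*% solve(XtVX, t(X) %*% Vinv)
  -0.5 * (as.numeric(ld$modulus) + log(XtVX[1, 1]) +
            drop(crossprod(y, P %*% y)))
}

## Coarse-to-fine 2-D grid maximizer of the restricted likelihood over
## (sigma2_g, sigma2_e); final step is `step_frac * var(y)` in each axis.
reml_grid_oracle <- function(y, zi, w, G, step_frac = 1e-3) {
  vy <- var(y)
  eval_grid <- function(sg_grid, se_grid) {
    best <- c(NA, NA); best_ll <- -Inf
    for (sg in sg_grid) for (se in se_grid) {
      ll <- reml_loglik_oracle(sg, se, y, zi, w, G)
      if (ll > best_ll) { best_ll <- ll; best <- c(sg, se) }
    }
    best
  }
  ## coarse pass over (0, 6 var(y)] incl. a near-zero point for boundary
  ## optima, then a fine pass around the coarse winner
  coarse_pts <- c(1e-8, seq(0.02, 6, by = 0.08)) * vy
  coarse <- eval_grid(coarse_pts, coarse_pts)
  fine_axis <- function(center)
    c(1e-8, seq(max(step_frac, center / vy - 0.12),
                center / vy + 0.12, by = step_frac)) * vy
  est <- eval_grid(fine_axis(coarse[1]), fine_axis(coarse[2]))
  list(sigma2_g = est[1], sigma2_e = est[2], step = step_frac * vy)
}

## Scalar-loop VanRaden method-1 oracle.
grm_loop_oracle <- function(calls, p) {
  n <- nrow(calls); m <- ncol(calls)
  denom <- 0
  for (j in seq_len(m)) denom <- denom + 2 * p[j] * (1 - p[j])
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0
    for (j in seq_len(m))
      acc <- acc + (calls[i, j] - 2 * p[j]) * (calls[k, j] - 2 * p[j])
    G[i, k] <- acc / denom
  }
  G
}

## Small random GBLUP instance on a genotype-derived relationship matrix.
random_instance <- function(q, seed, bivariate = FALSE) {
  set.seed(seed)
  m <- 50L
  p0 <- runif(m, 0.1, 0.5)
  calls <- matrix(rbinom(q * m, 2L, rep(p0, each = q)), nrow = q)
  rownames(calls) <- sprintf("id%03d", seq_len(q))
  colnames(calls) <- sprintf("s%03d", seq_len(m))
  keep <- apply(calls, 2, function(x) length(unique(x)) > 1L)
  calls <- calls[, keep, drop = FALSE]
  grm <- vanraden_grm(calls, epsilon = 1e-3)
  n <- max(4L, q - sample.int(3L, 1L) + 1L)  # some individuals unphenotyped
  rec <- sort(sample.int(q, n))
  r2 <- runif(n, 0.3, 0.95)
  out <- list(grm = grm, ids = rownames(calls)[rec],
              w = (1 - r2) / r2, r2 = r2, zi = rec,
              y = rnorm(n, 0, 2))
  if (bivariate) out$ti <- sample(rep(1:2, length.out = n))
  out
}

## One-call simulation -> QC -> GRM pipeline at test scale.
study_to_grm <- function(study, epsilon = 1e-6) {
  qc <- qc_genotypes(study$genotypes)
  G <- vanraden_grm(qc$genotypes, epsilon = epsilon)
  drp <- study$drp[study$drp$id %in% rownames(qc$genotypes$calls), ,
                   drop = FALSE]
  list(grm = G, drp = drp, genotypes = qc$genotypes)
}
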