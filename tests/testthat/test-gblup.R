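make_drp <- function(inst, bivariate = FALSE) {
  data.frame(id = inst$ids,
             pop = if (bivariate) c("pop1", "pop2")[inst$ti] else "pop1",
             trait = "t", drp = inst$y,
             reliability = inst$r2, stringsAsFactors = FALSE)
}

test_that("single-trait MME solutions equal the dense GLS/BLUP oracle", {
  inst <- random_instance(q = 8, seed = 101)
  sg <- 1.3; se <- 0.8
  fit <- gblup(make_drp(inst), inst$grm, model = "single",
               vc = list(sigma2_g = sg, sigma2_e = se))
  orc <- gls_oracle_single(inst$y, inst$zi, inst$w, inst$grm$mat, sg, se)
  expect_equal(unname(coef(fit)), orc$mu, tolerance = 1e-8)
  expect_equal(unname(fit$dgv[, 1]), orc$g, tolerance = 1e-8)
})

test_that("with no genetic signal the fit collapses to a weighted mean", {
  inst <- random_instance(q = 10, seed = 102)
  fit <- gblup(make_drp(inst), inst$grm, model = "single",
               vc = list(sigma2_g = 1e-8, sigma2_e = 1))
  expect_lt(max(abs(fit$dgv)), 1e-5)
  wmean <- sum(inst$y / inst$w) / sum(1 / inst$w)
  expect_equal(unname(coef(fit)), wmean, tolerance = 1e-6)
})

test_that("shifting every record shifts the mean, not the DGV", {
  inst <- random_instance(q = 9, seed = 103)
  d <- make_drp(inst)
  vc <- list(sigma2_g = 0.9, sigma2_e = 1.4)
  f0 <- gblup(d, inst$grm, model = "single", vc = vc)
  d$drp <- d$drp + 5
  f1 <- gblup(d, inst$grm, model = "single", vc = vc)
  expect_equal(unname(coef(f1)), unname(coef(f0)) + 5, tolerance = 1e-8)
  expect_equal(f1$dgv, f0$dgv, tolerance = 1e-8)
})

test_that("two-trait MME solutions equal the Kronecker-expanded GLS oracle", {
  inst <- random_instance(q = 6, seed = 104, bivariate = TRUE)
  G0 <- matrix(c(1.2, 0.5, 0.5, 0.7), 2)
  se <- c(0.9, 1.1)
  fit <- gblup(make_drp(inst, bivariate = TRUE), inst$grm,
               model = "bivariate", vc = list(G0 = G0, sigma2_e = se))
  orc <- gls_oracle_bivariate(inst$y, inst$zi, inst$ti, inst$w,
                              inst$grm$mat, G0, se)
  expect_equal(unname(coef(fit)), orc$mu, tolerance = 1e-8)
  expect_equal(unname(fit$dgv[, 1]), orc$g1, tolerance = 1e-8)
  expect_equal(unname(fit$dgv[, 2]), orc$g2, tolerance = 1e-8)
})

test_that("zero genetic covariance decouples the two traits", {
  inst <- random_instance(q = 12, seed = 105, bivariate = TRUE)
  d <- make_drp(inst, bivariate = TRUE)
  G0 <- matrix(c(1.1, 0, 0, 0.6), 2)
  se <- c(1.0, 0.8)
  fb <- gblup(d, inst$grm, model = "bivariate",
              vc = list(G0 = G0, sigma2_e = se))
  f1 <- gblup(d[d$pop == "pop1", ], inst$grm, model = "single",
              vc = list(sigma2_g = G0[1, 1], sigma2_e = se[1]))
  f2 <- gblup(d[d$pop == "pop2", ], inst$grm, model = "single",
              vc = list(sigma2_g = G0[2, 2], sigma2_e = se[2]))
  expect_lt(max(abs(fb$dgv[, "pop1"] - f1$dgv[, 1])), 1e-6)
  expect_lt(max(abs(fb$dgv[, "pop2"] - f2$dgv[, 1])), 1e-6)
})

test_that("relabelling the two traits swaps the solution symmetrically", {
  inst <- random_instance(q = 8, seed = 106, bivariate = TRUE)
  d <- make_drp(inst, bivariate = TRUE)
  G0 <- matrix(c(1.3, 0.4, 0.4, 0.8), 2)
  se <- c(0.7, 1.2)
  fit <- gblup(d, inst$grm, model = "bivariate",
               vc = list(G0 = G0, sigma2_e = se))
  d2 <- d
  d2$pop <- ifelse(d$pop == "pop1", "pop2", "pop1")
  fit2 <- gblup(d2, inst$grm, model = "bivariate",
                vc = list(G0 = G0[2:1, 2:1], sigma2_e = se[2:1]))
  expect_equal(unname(coef(fit2)), unname(coef(fit))[2:1], tolerance = 1e-8)
  expect_equal(unname(fit2$dgv[, "pop1"]), unname(fit$dgv[, "pop2"]),
               tolerance = 1e-8)
})

test_that("a singular G0 is rejected", {
  inst <- random_instance(q = 6, seed = 107, bivariate = TRUE)
  G0 <- matrix(c(1, 1, 1, 1), 2)
  expect_error(gblup(make_drp(inst, TRUE), inst$grm, model = "bivariate",
                     vc = list(G0 = G0, sigma2_e = c(1, 1))), "singular")
})

test_that("REML matches the grid-search maximizer on a toy instance", {
  inst <- random_instance(q = 8, seed = 108)
  d <- make_drp(inst)
  fit <- gblup(d, inst$grm, model = "single", tol = 1e-10)
  grid <- reml_grid_oracle(inst$y, inst$zi, inst$w, inst$grm$mat)
  expect_lt(abs(fit$vc$sigma2_g - grid$sigma2_g), grid$step)
  expect_lt(abs(fit$vc$sigma2_e - grid$sigma2_e), grid$step)
})

test_that("pure EM-REML never decreases the restricted likelihood", {
  inst <- random_instance(q = 15, seed = 109)
  fit <- suppressWarnings(
    gblup(make_drp(inst), inst$grm, model = "single", method = "em",
          max_iter = 60, tol = 1e-10))
  tr <- fit$vc$loglik_trace
  tr <- tr[is.finite(tr)]
  expect_true(all(diff(tr) > -1e-8))

  inst2 <- random_instance(q = 14, seed = 110, bivariate = TRUE)
  fit2 <- suppressWarnings(
    gblup(make_drp(inst2, TRUE), inst2$grm, model = "bivariate",
          method = "em", max_iter = 60, tol = 1e-10))
  tr2 <- fit2$vc$loglik_trace
  tr2 <- tr2[is.finite(tr2)]
  expect_true(all(diff(tr2) > -1e-8))
})

test_that("AI-REML agrees with pure EM-REML at convergence", {
  inst <- random_instance(q = 20, seed = 111)
  d <- make_drp(inst)
  f_ai <- gblup(d, inst$grm, model = "single", method = "ai", tol = 1e-10)
  f_em <- gblup(d, inst$grm, model = "single", method = "em",
                max_iter = 2000, tol = 1e-10)
  expect_equal(f_ai$vc$sigma2_g, f_em$vc$sigma2_g, tolerance = 1e-3)
  expect_equal(f_ai$vc$sigma2_e, f_em$vc$sigma2_e, tolerance = 1e-3)
})

test_that("near-noiseless records drive the fitted record noise to zero", {
  cfg <- sim_config(n_ind_pop1 = 300, n_ind_pop2 = 2, n_snps = 600,
                    reliability_spec_pop1 = 0.999,
                    n_split_generations = 0,
                    genotype_missing_rate = 0, seed = 13)
  st <- sim_study(cfg)
  ## pooled SNP filter: the true breeding values carry every polymorphic
  ## SNP's effect, so the GRM panel must keep them all
  geno <- filter_snps(st$genotypes, per_population = FALSE)$genotypes
  G <- vanraden_grm(geno)
  d1 <- st$drp[st$drp$pop == "pop1", ]
  fit <- gblup(d1, G, model = "single", tol = 1e-6)
  ## fitted residual variance of a record is w * sigma2_e with
  ## w = (1 - 0.999)/0.999; relative to the genetic variance it vanishes
  w <- drp_weights(0.999)
  expect_lt(w * fit$vc$sigma2_e / fit$vc$sigma2_g, 0.01)
})

test_that("individuals without records receive DGV through the GRM", {
  inst <- random_instance(q = 12, seed = 112)
  fit <- gblup(make_drp(inst), inst$grm, model = "single",
               vc = list(sigma2_g = 1, sigma2_e = 1))
  expect_equal(nrow(fit$dgv), 12)
  unphen <- setdiff(rownames(fit$dgv), inst$ids)
  if (length(unphen) > 0)
    expect_true(all(is.finite(fit$dgv[unphen, 1])))
  expect_error(predict(fit, ids = "no_such_id"), "not in the fitted GRM")
})

test_that("gblup accessors and simulate() behave like a model object", {
  inst <- random_instance(q = 10, seed = 113, bivariate = TRUE)
  d <- make_drp(inst, TRUE)
  fit <- gblup(d, inst$grm, model = "bivariate", tol = 1e-6)
  expect_equal(fitted(fit) + residuals(fit), d$drp, tolerance = 1e-10)
  expect_s3_class(summary(fit), "summary.gblup")
  expect_equal(attr(logLik(fit), "df"), 5)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 3))
  expect_true(all(is.finite(as.matrix(sims))))
})
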