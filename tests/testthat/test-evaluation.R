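phen_table <- function(ids, pop, drp = rnorm(length(ids)),
                       reliability = 0.6) {
  data.frame(id = ids, pop = pop, trait = "t", drp = drp,
             reliability = reliability, stringsAsFactors = FALSE)
}

test_that("forward split takes the youngest fifth per population", {
  ids <- sprintf("a%02d", 1:10)
  calls <- matrix(rbinom(10 * 12, 2, 0.5), 10, 12,
                  dimnames = list(ids, paste0("s", 1:12)))
  g <- genotype_matrix(calls, rep("pop1", 10),
                       as.Date(sprintf("%d-06-01", 2001:2010)))
  sp <- forward_split(phen_table(ids, rep("pop1", 10)), g, ratio = 0.2)
  expect_setequal(sp$validation_ids, c("a09", "a10"))
  expect_setequal(union(sp$reference_ids, sp$validation_ids), ids)
  expect_length(intersect(sp$reference_ids, sp$validation_ids), 0)
})

test_that("a degenerate all-same-day split warns and falls back to id order", {
  ids <- sprintf("b%02d", 1:5)
  calls <- matrix(rbinom(5 * 10, 2, 0.5), 5, 10,
                  dimnames = list(ids, paste0("s", 1:10)))
  g <- genotype_matrix(calls, rep("pop1", 5), rep(as.Date("2010-01-01"), 5))
  expect_warning(sp <- forward_split(phen_table(ids, rep("pop1", 5)), g),
                 "birth date")
  expect_length(sp$validation_ids, 1)
})

test_that("each population hits the target validation fraction", {
  cfg <- sim_config(n_ind_pop1 = 100, n_ind_pop2 = 100, n_snps = 50,
                    seed = 31)
  st <- sim_study(cfg)
  sp <- forward_split(st$drp, st$genotypes, ratio = 0.2)
  for (p in c("pop1", "pop2")) {
    ids_p <- st$drp$id[st$drp$pop == p]
    frac <- length(intersect(sp$validation_ids, ids_p)) / length(ids_p)
    expect_lt(abs(frac - 0.2), 0.02)
    ## everyone in the validation set is younger than everyone in reference
    bd <- st$genotypes$birth_date
    expect_gte(min(bd[intersect(sp$validation_ids, ids_p)]),
               max(bd[intersect(sp$reference_ids, ids_p)]) - 0)
  }
})

test_that("cross-validation folds are stratified partitions", {
  d <- phen_table(sprintf("c%02d", 1:20), rep(c("pop1", "pop2"), each = 10))
  plans <- cv_plan(d, k = 5, replicates = 2, seed = 7)
  expect_length(plans, 10)
  for (r in 1:2) {
    rep_plans <- Filter(function(p) p$replicate == r, plans)
    vals <- lapply(rep_plans, `[[`, "validation_ids")
    expect_setequal(unlist(vals), d$id)           # union covers everyone
    expect_equal(anyDuplicated(unlist(vals)), 0)  # pairwise disjoint
    for (v in vals) {
      expect_equal(sum(v %in% d$id[d$pop == "pop1"]), 2)
      expect_equal(sum(v %in% d$id[d$pop == "pop2"]), 2)
    }
  }
  ## reproducible for a fixed seed, different across replicates
  plans2 <- cv_plan(d, k = 5, replicates = 2, seed = 7)
  expect_identical(lapply(plans, `[[`, "validation_ids"),
                   lapply(plans2, `[[`, "validation_ids"))
  expect_false(identical(sort(plans[[1]]$validation_ids),
                         sort(plans[[6]]$validation_ids)))
  expect_error(cv_plan(d, k = 1), "k must be")
  expect_error(cv_plan(d[1:3, ], k = 5), "fewer")
})

test_that("accuracy follows acc = cor / rbar with hand-checked values", {
  expect_equal(prediction_accuracy(c(1, 2, 3), rep(1, 3),
                                   c(1, 2, 3))$accuracy, 1)
  expect_equal(prediction_accuracy(c(1, 2, 3), rep(1, 3),
                                   c(-1, -2, -3))$accuracy, -1)
  ## hand Pearson: cov*3 = 4.7, var products 5 * 4.5 -> cor = 4.7/sqrt(22.5)
  res <- prediction_accuracy(c(1, 2, 3, 4), rep(0.64, 4),
                             c(1.1, 1.9, 3.2, 3.8))
  expect_equal(res$correlation, 4.7 / sqrt(22.5), tolerance = 1e-12)
  expect_equal(res$r_bar, 0.8)
  expect_equal(res$accuracy, 4.7 / sqrt(22.5) / 0.8, tolerance = 1e-12)
  ## the two rbar conventions differ for heterogeneous reliabilities
  r2 <- c(0.4, 0.9, 0.6, 0.7)
  a1 <- prediction_accuracy(1:4, r2, c(2, 1, 4, 3), "mean_sqrt")
  a2 <- prediction_accuracy(1:4, r2, c(2, 1, 4, 3), "sqrt_mean")
  expect_equal(a1$r_bar, mean(sqrt(r2)))
  expect_equal(a2$r_bar, sqrt(mean(r2)))
  expect_warning(prediction_accuracy(c(1, 1, 1), rep(0.5, 3), 1:3), "zero")
})

test_that("unbiasedness is the DRP-on-DGV regression slope", {
  y <- c(1.2, 0.3, 2.5, -0.4, 1.1)
  expect_equal(prediction_unbiasedness(y, y), 1)
  expect_equal(prediction_unbiasedness(y, 0.5 * y), 2)
  set.seed(2)
  g <- rnorm(8); yy <- rnorm(8)
  b1 <- prediction_unbiasedness(yy, g)
  for (c in c(0.25, 2, -1.5))
    expect_equal(prediction_unbiasedness(yy, c * g), b1 / c)
  expect_warning(prediction_unbiasedness(y, rep(1, 5)), "zero")
})

test_that("scenario runs never see validation records", {
  cfg <- sim_config(n_ind_pop1 = 60, n_ind_pop2 = 60, n_snps = 300,
                    seed = 33)
  st <- sim_study(cfg)
  pg <- study_to_grm(st)
  sp <- forward_split(pg$drp, pg$genotypes)
  m1 <- run_scenarios(pg$drp, pg$grm, sp, scenarios = c("own", "joint"),
                      tol = 1e-6)
  ## the audited reference sets exclude every validation id
  for (refs in attr(m1, "reference_ids"))
    expect_length(intersect(refs, sp$validation_ids), 0)
  ## perturbing validation DRP leaves the fitted models untouched:
  ## the joint fit's genetic-correlation estimate cannot change
  drp2 <- pg$drp
  sel <- drp2$id %in% sp$validation_ids
  set.seed(1)
  drp2$drp[sel] <- drp2$drp[sel] + rnorm(sum(sel), 0, 20)
  m2 <- run_scenarios(drp2, pg$grm, sp, scenarios = c("own", "joint"),
                      tol = 1e-6)
  expect_identical(m1$rg_estimate[m1$scenario == "joint"],
                   m2$rg_estimate[m2$scenario == "joint"])
  ## ... while the validation-side statistics do change
  expect_false(isTRUE(all.equal(m1$accuracy, m2$accuracy)))
})

test_that("metrics tables carry the Tables 3/4 shape and summarize cleanly", {
  cfg <- sim_config(n_ind_pop1 = 50, n_ind_pop2 = 50, n_snps = 250,
                    seed = 34)
  st <- sim_study(cfg)
  pg <- study_to_grm(st)
  plans <- cv_plan(pg$drp, k = 3, replicates = 2, seed = 5)
  m <- run_scenarios(pg$drp, pg$grm, plans[1:3], scenarios = "own",
                     tol = 1e-5)
  expect_setequal(unique(m$validation_pop), c("pop1", "pop2"))
  expect_true(all(c("accuracy", "unbiasedness", "r_bar", "fold",
                    "replicate", "n_validation") %in% colnames(m)))
  s <- summarize_metrics(m)
  expect_true(all(c("accuracy_mean", "accuracy_sd", "unbiasedness_mean",
                    "unbiasedness_sd") %in% colnames(s)))
  expect_equal(unique(s$n_splits), 3)
})
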