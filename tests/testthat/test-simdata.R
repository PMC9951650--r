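test_that("identical configuration and seed give bit-identical output", {
  cfg <- sim_config(n_ind_pop1 = 30, n_ind_pop2 = 30, n_snps = 100, seed = 11)
  a <- sim_study(cfg)
  b <- sim_study(cfg)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$drp, b$drp)
  expect_identical(a$state$effects_pop1, b$state$effects_pop1)
})

test_that("no divergence with perfect effect correlation collapses the two populations", {
  cfg <- sim_config(n_ind_pop1 = 100, n_ind_pop2 = 100, n_snps = 500,
                    n_split_generations = 0, true_rg = 1,
                    genotype_missing_rate = 0, seed = 5)
  sim <- simulate_populations(cfg)
  ## effects identical up to the per-population rescaling
  expect_equal(cor(sim$state$effects_pop1, sim$state$effects_pop2), 1,
               tolerance = 1e-12)
  geno <- filter_snps(sim$genotypes)$genotypes
  G <- vanraden_grm(geno)
  rs <- relationship_summary(G, geno$pop)
  within_means <- rs$mean[rs$type == "within"]
  between_mean <- rs$mean[rs$type == "between"]
  expect_lt(abs(between_mean - mean(within_means)), 0.02)
})

test_that("uncorrelated effects come out empirically uncorrelated", {
  cfg <- sim_config(n_ind_pop1 = 50, n_ind_pop2 = 50, n_snps = 1000,
                    true_rg = 0, n_split_generations = 0, seed = 9)
  sim <- simulate_populations(cfg)
  expect_lt(abs(cor(sim$state$effects_pop1, sim$state$effects_pop2)),
            3 / sqrt(cfg$n_snps))
})

test_that("drifted populations are less related between than within", {
  cfg <- sim_config(n_ind_pop1 = 200, n_ind_pop2 = 200, n_snps = 1000,
                    n_split_generations = 20, seed = 1)
  sim <- simulate_populations(cfg)
  pg <- study_to_grm(list(genotypes = sim$genotypes,
                          drp = data.frame(id = rownames(sim$genotypes$calls),
                                           pop = sim$genotypes$pop,
                                           trait = "t", drp = 0,
                                           reliability = 0.5)))
  rs <- relationship_summary(pg$grm, pg$genotypes$pop)
  between <- rs$mean[rs$type == "between"]
  for (wm in rs$mean[rs$type == "within"]) expect_lt(between, wm)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_snps = 5), "n_snps")
  expect_error(sim_config(n_ind_pop1 = 1), class = "simpleError")
  expect_error(sim_config(true_rg = 1.2), "true_rg")
  expect_error(sim_config(reliability_spec_pop1 = 1.0), "reliability")
})

test_that("DRP noise vanishes as reliability approaches one", {
  cfg <- sim_config(n_ind_pop1 = 200, n_ind_pop2 = 200, n_snps = 400,
                    reliability_spec_pop1 = 0.999,
                    reliability_spec_pop2 = 0.999, seed = 2)
  st <- sim_study(cfg)
  expect_gt(cor(st$drp$drp, st$state$tbv[st$drp$id]), 0.99)
})

test_that("fixed reliability calibrates the tbv-on-drp regression", {
  ## regression slope of tbv on drp estimates the reliability r2
  cfg <- sim_config(n_ind_pop1 = 1000, n_ind_pop2 = 2, n_snps = 300,
                    reliability_spec_pop1 = 0.6, seed = 21)
  st <- sim_study(cfg)
  d1 <- st$drp[st$drp$pop == "pop1", ]
  slope <- coef(lm(st$state$tbv[d1$id] ~ d1$drp))[2]
  expect_lt(abs(slope - 0.6), 0.05)
})

test_that("Beta reliability specs hit their target means", {
  ## moment-matched Beta(m*k, (1-m)*k) with k = 50, means from the two
  ## population regimes (progeny-tested bulls vs lower-reliability records)
  k <- 50
  cfg <- sim_config(n_ind_pop1 = 500, n_ind_pop2 = 500, n_snps = 100,
                    reliability_spec_pop1 = c(0.945 * k, (1 - 0.945) * k),
                    reliability_spec_pop2 = c(0.656 * k, (1 - 0.656) * k),
                    seed = 3)
  st <- sim_study(cfg)
  expect_lt(abs(mean(st$drp$reliability[st$drp$pop == "pop1"]) - 0.945), 0.02)
  expect_lt(abs(mean(st$drp$reliability[st$drp$pop == "pop2"]) - 0.656), 0.02)
})

test_that("a study round-trips through its files, preserving missingness", {
  cfg <- sim_config(n_ind_pop1 = 5, n_ind_pop2 = 5, n_snps = 20,
                    genotype_missing_rate = 0, seed = 4)
  st <- sim_study(cfg)
  st$genotypes$calls[cbind(c(1, 3, 7), c(2, 5, 11))] <- NA  # 3 missing cells
  dir <- withr::local_tempdir()
  write_study(st$genotypes, st$state, st$drp, dir, config = cfg)
  back <- read_study(dir)
  expect_identical(back$genotypes$calls, st$genotypes$calls)
  expect_equal(sum(is.na(back$genotypes$calls)), 3)
  expect_equal(back$genotypes$pop, st$genotypes$pop)
  expect_equal(back$genotypes$birth_date, st$genotypes$birth_date)
  expect_equal(back$drp$drp, st$drp$drp)
  expect_equal(back$state$tbv, st$state$tbv)
  ## refuses to overwrite without the flag
  expect_error(write_study(st$genotypes, st$state, st$drp, dir), "overwrite")
  ## truth withheld on request
  dir2 <- withr::local_tempdir()
  write_study(st$genotypes, st$state, st$drp, dir2, export_truth = FALSE)
  expect_false(file.exists(file.path(dir2, "truth.tsv")))
})

test_that("PLINK-RAW-style additive files are accepted", {
  dir <- withr::local_tempdir()
  raw <- data.frame(FID = c("fam1", "fam1", "fam2"),
                    IID = c("a", "b", "c"), PAT = 0, MAT = 0, SEX = 1,
                    PHENOTYPE = -9,
                    snpA_G = c(0, 1, 2), snpB_T = c(2, NA, 1))
  path <- file.path(dir, "geno.raw")
  write.table(raw, path, sep = " ", quote = FALSE, row.names = FALSE)
  g <- read_genotypes(path)
  expect_equal(rownames(g$calls), c("a", "b", "c"))
  expect_equal(unname(g$pop), c("fam1", "fam1", "fam2"))
  expect_equal(unname(g$calls[, "snpB_T"]), c(2, NA, 1))
})

test_that("SNP-level effect correlation is recovered across replicates", {
  for (rg in c(0.15, 0.45, 0.72)) {
    cors <- vapply(seq_len(50), function(r) {
      cfg <- sim_config(n_ind_pop1 = 20, n_ind_pop2 = 20, n_snps = 2000,
                        n_split_generations = 0, true_rg = rg,
                        genotype_missing_rate = 0, seed = 1000 * rg + r)
      sim <- simulate_populations(cfg)
      cor(sim$state$effects_pop1, sim$state$effects_pop2)
    }, numeric(1))
    expect_lt(abs(mean(cors) - rg), 0.02)
  }
})
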