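#' Simulation configuration for a two-population genomic prediction study
#'
#' Collects and validates every parameter of the synthetic-data generator:
#' population sizes, marker panel size, founder allele-frequency range, drift
#' generations after the populations split, the true between-population
#' (SNP-level) genetic correlation encoding genotype-by-environment
#' interaction, per-population additive variances, reliability distributions
#' of the de-regressed proofs (DRP), genotype missingness and birth years.
#'
#' The defaults describe the study conditions emulated throughout the package:
#' two populations of 300 genotyped individuals, 1500 SNPs, 20 generations of
#' drift at effective size 100 (F_ST about 0.1, enough to push between-
#' population genomic relationships below the within-population means), a
#' between-population genetic correlation of 0.7 (milk-production-trait
#' regime), DRP reliabilities of 0.55 for population 1 (cow-dominated,
#' low-reliability) and 0.94 for population 2 (progeny-tested bulls), and
#' additive variances on deliberately different scales (100 vs 25) because the
#' two populations express the trait on different DRP scales.
#'
#' @param n_ind_pop1,n_ind_pop2 number of genotyped individuals per population.
#' @param n_snps number of biallelic SNPs (>= 10).
#' @param founder_maf_range length-2 numeric in (0, 0.5]: founder allele
#'   frequencies are drawn uniformly from this range.
#' @param n_split_generations generations of independent random mating after
#'   the populations diverge from the common founder pool (0 = no divergence).
#' @param effective_size_per_generation effective population size governing
#'   drift per generation.
#' @param true_rg true SNP-effect correlation between the populations, in
#'   \[-1, 1\]. Values below 0.8 encode genotype-by-environment interaction.
#' @param sigma2_g_pop1,sigma2_g_pop2 additive genetic variances (trait
#'   units squared) that the true breeding values are scaled to per population.
#' @param reliability_spec_pop1,reliability_spec_pop2 either a single value in
#'   (0, 0.999] (fixed DRP reliability) or a length-2 vector of Beta(a, b)
#'   shape parameters to draw per-individual reliabilities from.
#' @param genotype_missing_rate proportion of genotype calls masked as
#'   missing, in \[0, 1).
#' @param birth_year_range length-2 integer vector; birth dates are drawn
#'   uniformly over these years (day uniform within the year).
#' @param trait_name name used for the simulated trait in DRP tables.
#' @param seed integer seed; identical configuration and seed give
#'   bit-identical output.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_populations()], [generate_drp()], [sim_study()]
#' @export
sim_config <- function(n_ind_pop1 = 300, n_ind_pop2 = 300, n_snps = 1500,
                       founder_maf_range = c(0.05, 0.5),
                       n_split_generations = 20,
                       effective_size_per_generation = 100,
                       true_rg = 0.7,
                       sigma2_g_pop1 = 100, sigma2_g_pop2 = 25,
                       reliability_spec_pop1 = 0.55,
                       reliability_spec_pop2 = 0.94,
                       genotype_missing_rate = 0.02,
                       birth_year_range = c(2000L, 2018L),
                       trait_name = "trait",
                       seed = 1L) {
  cfg <- list(n_ind_pop1 = as.integer(n_ind_pop1),
              n_ind_pop2 = as.integer(n_ind_pop2),
              n_snps = as.integer(n_snps),
              founder_maf_range = as.numeric(founder_maf_range),
              n_split_generations = as.integer(n_split_generations),
              effective_size_per_generation = as.integer(effective_size_per_generation),
              true_rg = as.numeric(true_rg),
              sigma2_g_pop1 = as.numeric(sigma2_g_pop1),
              sigma2_g_pop2 = as.numeric(sigma2_g_pop2),
              reliability_spec_pop1 = as.numeric(reliability_spec_pop1),
              reliability_spec_pop2 = as.numeric(reliability_spec_pop2),
              genotype_missing_rate = as.numeric(genotype_missing_rate),
              birth_year_range = as.integer(birth_year_range),
              trait_name = as.character(trait_name),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_ind_pop1 >= 2, cfg$n_ind_pop2 >= 2)
  if (cfg$n_snps < 10)
    stop("n_snps must be at least 10 (degenerate covariance estimation below)")
  r <- cfg$founder_maf_range
  if (length(r) != 2 || any(r <= 0) || any(r > 0.5) || r[1] > r[2])
    stop("founder_maf_range must be an increasing pair in (0, 0.5]")
  if (cfg$true_rg < -1 || cfg$true_rg > 1)
    stop("true_rg must lie in [-1, 1]")
  if (cfg$sigma2_g_pop1 <= 0 || cfg$sigma2_g_pop2 <= 0)
    stop("additive variances must be positive")
  for (spec in list(cfg$reliability_spec_pop1, cfg$reliability_spec_pop2)) {
    if (length(spec) == 1) {
      if (spec <= 0 || spec > 0.999)
        stop("fixed reliability must lie in (0, 0.999]")
    } else if (length(spec) == 2) {
      if (any(spec <= 0)) stop("Beta reliability parameters must be positive")
    } else stop("reliability spec must have length 1 (fixed) or 2 (Beta a, b)")
  }
  if (cfg$genotype_missing_rate < 0 || cfg$genotype_missing_rate >= 1)
    stop("genotype_missing_rate must lie in [0, 1)")
  if (cfg$n_split_generations < 0) stop("n_split_generations must be >= 0")
  if (cfg$effective_size_per_generation < 1)
    stop("effective_size_per_generation must be >= 1")
  if (length(cfg$birth_year_range) != 2 ||
      cfg$birth_year_range[1] > cfg$birth_year_range[2])
    stop("birth_year_range must be an increasing pair of years")
  invisible(cfg)
}

#' Construct a genotype matrix object
#'
#' Container for additive-coded SNP genotypes with per-individual population
#' labels and (optionally) birth dates. Calls are 0/1/2 counts of the
#' alternative allele with `NA` for missing.
#'
#' @param calls integer/numeric matrix, individuals in rows (rownames are the
#'   unique individual ids), SNPs in columns (colnames are SNP ids).
#' @param pop character vector of population labels, one per row of `calls`.
#' @param birth_date optional `Date` vector, one per individual.
#' @return An object of class `genotypes` with elements `calls`, `pop`,
#'   `birth_date`.
#' @export
genotype_matrix <- function(calls, pop, birth_date = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) stop("calls must have individual ids as rownames")
  if (anyDuplicated(rownames(calls))) stop("individual ids must be unique")
  if (is.null(colnames(calls))) colnames(calls) <- paste0("snp_", seq_len(ncol(calls)))
  ok <- is.na(calls) | calls %in% c(0, 1, 2)
  if (!all(ok)) stop("non-missing genotype calls must be 0, 1 or 2")
  pop <- as.character(pop)
  if (length(pop) != nrow(calls)) stop("one population label per individual required")
  names(pop) <- rownames(calls)
  if (!is.null(birth_date)) {
    birth_date <- as.Date(birth_date)
    if (length(birth_date) != nrow(calls))
      stop("one birth date per individual required")
    names(birth_date) <- rownames(calls)
  }
  structure(list(calls = calls, pop = pop, birth_date = birth_date),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d SNPs\n",
              nrow(x$calls), ncol(x$calls)))
  tb <- table(x$pop)
  cat("Populations:", paste(sprintf("%s (n=%d)", names(tb), tb), collapse = ", "), "\n")
  cat(sprintf("Missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$calls)

## Drift one allele-frequency vector through g generations of binomial
## sampling at effective size Ne (2*Ne gametes per generation).
drift_freqs <- function(p, generations, ne) {
  for (g in seq_len(generations)) p <- stats::rbinom(length(p), 2L * ne, p) / (2 * ne)
  p
}

#' Simulate two diverged populations with correlated SNP effects
#'
#' Draws founder allele frequencies uniformly from the configured range, lets
#' the two populations drift independently for `n_split_generations`
#' generations of random mating at the configured effective size, and samples
#' Hardy-Weinberg genotypes at the resulting per-population frequencies.
#' Allele-substitution effects for population 2 are built from population 1's
#' effects as `a2 = rg * a1 + sqrt(1 - rg^2) * eps`, then each effect vector
#' is rescaled so that the variance of the true breeding values (TBV) in each
#' population equals its configured additive variance; effects are correlated
#' at the SNP level so that the bivariate model's genomic correlation is the
#' estimand by construction. TBV are computed from the complete (pre-
#' missingness) genotypes with the individual's own population's effects and
#' centered per population.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements `genotypes` (a [genotype_matrix()] with
#'   missingness already applied) and `state` (list with `effects_pop1`,
#'   `effects_pop2`, `tbv` named by individual, `true_rg`).
#' @export
simulate_populations <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  m <- config$n_snps
  n1 <- config$n_ind_pop1
  n2 <- config$n_ind_pop2
  p0 <- stats::runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  pA <- drift_freqs(p0, config$n_split_generations, config$effective_size_per_generation)
  pB <- drift_freqs(p0, config$n_split_generations, config$effective_size_per_generation)

  geno1 <- matrix(stats::rbinom(n1 * m, 2L, rep(pA, each = n1)), nrow = n1)
  geno2 <- matrix(stats::rbinom(n2 * m, 2L, rep(pB, each = n2)), nrow = n2)
  calls <- rbind(geno1, geno2)
  ids <- c(sprintf("P1_%04d", seq_len(n1)), sprintf("P2_%04d", seq_len(n2)))
  rownames(calls) <- ids
  colnames(calls) <- sprintf("snp_%05d", seq_len(m))
  pop <- rep(c("pop1", "pop2"), c(n1, n2))

  a1 <- stats::rnorm(m)
  a2 <- config$true_rg * a1 + sqrt(1 - config$true_rg^2) * stats::rnorm(m)
  tbv1_raw <- drop(calls[seq_len(n1), , drop = FALSE] %*% a1)
  tbv2_raw <- drop(calls[n1 + seq_len(n2), , drop = FALSE] %*% a2)
  v1 <- stats::var(tbv1_raw)
  v2 <- stats::var(tbv2_raw)
  if (v1 <= 0 || v2 <= 0)
    stop("degenerate simulation: true breeding values have zero variance")
  s1 <- sqrt(config$sigma2_g_pop1 / v1)
  s2 <- sqrt(config$sigma2_g_pop2 / v2)
  effects_pop1 <- a1 * s1
  effects_pop2 <- a2 * s2
  tbv <- c(tbv1_raw * s1 - mean(tbv1_raw * s1),
           tbv2_raw * s2 - mean(tbv2_raw * s2))
  names(tbv) <- ids

  ## birth dates: uniform year over the configured range, uniform day in year
  yrs <- sample(seq(config$birth_year_range[1], config$birth_year_range[2]),
                n1 + n2, replace = TRUE)
  doy <- sample.int(365L, n1 + n2, replace = TRUE)
  birth_date <- as.Date(sprintf("%d-01-01", yrs)) + (doy - 1L)

  if (config$genotype_missing_rate > 0) {
    mask <- stats::runif(length(calls)) < config$genotype_missing_rate
    calls[mask] <- NA_integer_
  }

  list(genotypes = genotype_matrix(calls, pop, birth_date),
       state = list(effects_pop1 = effects_pop1,
                    effects_pop2 = effects_pop2,
                    tbv = tbv,
                    true_rg = config$true_rg))
}

resolve_reliabilities <- function(spec, n) {
  r2 <- if (length(spec) == 1) rep(spec, n) else stats::rbeta(n, spec[1], spec[2])
  pmin(pmax(r2, 1e-3), 0.999)
}

#' Generate de-regressed-proof (DRP) records with per-record reliability
#'
#' One pseudo-phenotype per individual per trait: `drp_i = tbv_i + e_i` with
#' `e_i ~ N(0, sigma2_g * (1 - r2_i) / r2_i)` using the individual's own
#' population's additive variance, so that the reliability `r2_i` equals
#' `var(tbv) / var(drp)` in expectation and the residual weight
#' `(1 - r2) / r2` of the GBLUP models is exact by construction.
#'
#' @param state,genotypes the `state` and `genotypes` from
#'   [simulate_populations()].
#' @param config the [sim_config()] used.
#' @param seed integer seed for reliabilities and noise; defaults to
#'   `config$seed + 1`.
#' @return A data.frame (DRP table) with columns `id`, `pop`, `trait`, `drp`,
#'   `reliability`.
#' @export
generate_drp <- function(state, genotypes, config, seed = config$seed + 1L) {
  set.seed(seed)
  ids <- rownames(genotypes$calls)
  if (!all(ids %in% names(state$tbv))) stop("tbv missing for some individuals")
  pop <- genotypes$pop
  n <- length(ids)
  r2 <- numeric(n)
  r2[pop == "pop1"] <- resolve_reliabilities(config$reliability_spec_pop1,
                                             sum(pop == "pop1"))
  r2[pop == "pop2"] <- resolve_reliabilities(config$reliability_spec_pop2,
                                             sum(pop == "pop2"))
  s2g <- ifelse(pop == "pop1", config$sigma2_g_pop1, config$sigma2_g_pop2)
  noise_var <- s2g * (1 - r2) / r2
  drp <- state$tbv[ids] + stats::rnorm(n, 0, sqrt(noise_var))
  data.frame(id = ids, pop = pop, trait = config$trait_name,
             drp = unname(drp), reliability = r2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a complete study (genotypes, truth, DRP) in one call
#'
#' @param config a [sim_config()].
#' @return List with `genotypes`, `state`, `drp`, `config`.
#' @export
sim_study <- function(config = sim_config()) {
  sim <- simulate_populations(config)
  drp <- generate_drp(sim$state, sim$genotypes, config)
  list(genotypes = sim$genotypes, state = sim$state, drp = drp, config = config)
}

#' Write a simulated study to plain-text files
#'
#' Emits `genotypes.tsv` (header `id pop birth_date snp_...`, calls 0/1/2 with
#' `NA` for missing), `drp.tsv` (`id pop trait drp reliability`), `truth.tsv`
#' (per-SNP allele-substitution effects for both populations and per-
#' individual true breeding values, long format) and `config.json`. The files
#' round-trip losslessly through [read_genotypes()] / [read_drp()] /
#' [read_study()].
#'
#' @param genotypes,state,drp study components as returned by [sim_study()].
#' @param directory output directory, created if absent.
#' @param config optional [sim_config()] to record alongside the data.
#' @param overwrite refuse to overwrite existing files unless `TRUE`.
#' @param export_truth write `truth.tsv`? Set `FALSE` to withhold the truth.
#' @return Invisibly, the paths written.
#' @export
write_study <- function(genotypes, state, drp, directory, config = NULL,
                        overwrite = FALSE, export_truth = TRUE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, c("genotypes.tsv", "drp.tsv", "truth.tsv",
                                  "config.json"))
  names(paths) <- c("genotypes", "drp", "truth", "config")
  if (!overwrite && any(file.exists(paths[1:2])))
    stop("output files exist; use overwrite = TRUE to replace them")
  gdf <- data.frame(id = rownames(genotypes$calls), pop = genotypes$pop,
                    birth_date = if (is.null(genotypes$birth_date)) NA
                                 else as.character(genotypes$birth_date),
                    genotypes$calls, stringsAsFactors = FALSE,
                    check.names = FALSE)
  utils::write.table(gdf, paths["genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(drp, paths["drp"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (export_truth) {
    if (is.null(state)) stop("state required when export_truth = TRUE")
    tdf <- rbind(
      data.frame(kind = "effect", id = colnames(genotypes$calls),
                 value1 = state$effects_pop1, value2 = state$effects_pop2,
                 stringsAsFactors = FALSE),
      data.frame(kind = "tbv", id = names(state$tbv),
                 value1 = unname(state$tbv), value2 = NA_real_,
                 stringsAsFactors = FALSE))
    utils::write.table(tdf, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (file.exists(paths["truth"]) && overwrite) {
    unlink(paths["truth"])
  }
  if (!is.null(config))
    jsonlite::write_json(unclass(config), paths["config"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read an additive-coded genotype file
#'
#' Accepts the package's native TSV layout (`id pop birth_date snp_...`) or a
#' PLINK-RAW-style additive file (header starting `FID IID ...` followed by
#' per-SNP 0/1/2/NA columns; population taken from `FID`).
#'
#' @param path file path.
#' @return A [genotype_matrix()] object.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  cn <- colnames(df)
  if (identical(toupper(cn[1:2]), c("FID", "IID"))) {
    meta <- intersect(toupper(cn), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
    snp_cols <- cn[!(toupper(cn) %in% meta)]
    calls <- as.matrix(df[, snp_cols, drop = FALSE])
    rownames(calls) <- as.character(df[[which(toupper(cn) == "IID")[1]]])
    genotype_matrix(calls, pop = as.character(df[[which(toupper(cn) == "FID")[1]]]))
  } else {
    stopifnot(all(c("id", "pop") %in% cn))
    snp_cols <- setdiff(cn, c("id", "pop", "birth_date"))
    calls <- as.matrix(df[, snp_cols, drop = FALSE])
    rownames(calls) <- as.character(df$id)
    bd <- if ("birth_date" %in% cn && !all(is.na(df$birth_date)))
      as.Date(df$birth_date) else NULL
    genotype_matrix(calls, pop = df$pop, birth_date = bd)
  }
}

#' Read a DRP table (`id pop trait drp reliability`)
#' @param path file path.
#' @return A data.frame DRP table.
#' @export
read_drp <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("id", "pop", "trait", "drp", "reliability") %in% colnames(df)))
  df$id <- as.character(df$id)
  df
}

#' Read back a study written by [write_study()]
#' @param directory directory holding `genotypes.tsv`, `drp.tsv` and
#'   optionally `truth.tsv`.
#' @return List with `genotypes`, `drp`, and `state` (NULL if no truth file).
#' @export
read_study <- function(directory) {
  genotypes <- read_genotypes(file.path(directory, "genotypes.tsv"))
  drp <- read_drp(file.path(directory, "drp.tsv"))
  state <- NULL
  tp <- file.path(directory, "truth.tsv")
  if (file.exists(tp)) {
    tdf <- utils::read.table(tp, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    eff <- tdf[tdf$kind == "effect", ]
    tbv <- tdf[tdf$kind == "tbv", ]
    state <- list(effects_pop1 = eff$value1, effects_pop2 = eff$value2,
                  tbv = stats::setNames(tbv$value1, tbv$id))
  }
  list(genotypes = genotypes, drp = drp, state = state)
}
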