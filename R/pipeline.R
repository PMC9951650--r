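## End-to-end orchestration: simulate -> qc -> grm -> split -> fit/evaluate,
## with one config object, derived per-stage seeds and a provenance log.

#' Experiment configuration
#'
#' One validated configuration object driving [run_experiment()]: the
#' simulation settings, QC thresholds, GRM regularization, model options and
#' validation design. Unknown keys in any section are an error — silent typos
#' in thresholds are the main operator hazard.
#'
#' @param sim a [sim_config()].
#' @param qc list: `maf_min`, `snp_call_min`, `ind_call_min`,
#'   `per_population`, `impute`.
#' @param grm list: `epsilon`.
#' @param model list: `shared_residual`, `rbar_mode`, `method`, `tol`,
#'   `max_iter`.
#' @param validation list: `design` ("forward" or "cv"), `ratio` (forward),
#'   `k` and `replicates` (cv).
#' @param scenarios subset of `c("own", "cross", "joint")`.
#' @param seed global integer seed from which per-stage seeds are derived.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              qc = list(),
                              grm = list(),
                              model = list(),
                              validation = list(),
                              scenarios = c("own", "cross", "joint"),
                              seed = 1L) {
  merge_section <- function(defaults, given, name) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown))
      stop(sprintf("unknown %s config key(s): %s", name,
                   paste(unknown, collapse = ", ")))
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    sim = sim,
    qc = merge_section(list(maf_min = 0.01, snp_call_min = 0.90,
                            ind_call_min = 0.90, per_population = TRUE,
                            impute = "mean_round"), qc, "qc"),
    grm = merge_section(list(epsilon = 1e-6), grm, "grm"),
    model = merge_section(list(shared_residual = FALSE,
                               rbar_mode = "mean_sqrt", method = "ai",
                               tol = 1e-8, max_iter = 200L), model, "model"),
    validation = merge_section(list(design = "forward", ratio = 0.2,
                                    k = 5L, replicates = 10L),
                               validation, "validation"),
    scenarios = match.arg(scenarios, c("own", "cross", "joint"),
                          several.ok = TRUE),
    seed = as.integer(seed))
  stopifnot(inherits(cfg$sim, "sim_config"),
            cfg$validation$design %in% c("forward", "cv"))
  class(cfg) <- "experiment_config"
  cfg
}

## Deterministic per-stage seeds derived from the global seed, kept inside
## the 32-bit integer range so independent stage reruns stay reproducible.
stage_seed <- function(global_seed, stage) {
  stages <- c(simulate = 1L, qc = 2L, cv = 3L)
  ((as.numeric(global_seed) * 7919 + 104729 * stages[[stage]]) %%
     2147483647) |> as.integer()
}

#' Run a full simulated joint-prediction experiment
#'
#' Executes simulate -> QC -> GRM -> split -> fit/evaluate, writes every
#' intermediate artifact (genotypes, DRP, truth, QC report, GRM, metrics,
#' summary) plus a provenance log (config, derived seeds, stage timings,
#' file checksums) under `outdir`. Re-running the same config and seed
#' reproduces all outputs.
#'
#' @param config an [experiment_config()].
#' @param outdir output directory.
#' @param overwrite allow overwriting an existing study in `outdir`.
#' @param verbose log stage progress to stderr.
#' @return Invisibly, a list with `metrics`, `summary`, `qc_report`,
#'   `grm_summary`, `paths`.
#' @export
run_experiment <- function(config, outdir, overwrite = FALSE,
                           verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    log_msg("stage %-10s done in %6.2fs", stage, timings[[stage]])
    res
  }

  sim_cfg <- config$sim
  sim_cfg$seed <- stage_seed(config$seed, "simulate")
  study <- tick("simulate", sim_study(sim_cfg))
  tick("write", write_study(study$genotypes, study$state, study$drp, outdir,
                            config = sim_cfg, overwrite = overwrite))

  qc <- tick("qc", qc_genotypes(study$genotypes,
                                maf_min = config$qc$maf_min,
                                snp_call_min = config$qc$snp_call_min,
                                ind_call_min = config$qc$ind_call_min,
                                per_population = config$qc$per_population,
                                impute = config$qc$impute,
                                seed = stage_seed(config$seed, "qc")))
  utils::write.table(as.data.frame(qc$report),
                     file.path(outdir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  G <- tick("grm", vanraden_grm(qc$genotypes, epsilon = config$grm$epsilon))
  write_grm(G, file.path(outdir, "grm.tsv"))
  grm_summary <- relationship_summary(G, qc$genotypes$pop)
  utils::write.table(grm_summary, file.path(outdir, "grm_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## QC may drop individuals; evaluate on the survivors only
  drp <- study$drp[study$drp$id %in% rownames(qc$genotypes$calls), ,
                   drop = FALSE]
  split <- tick("split", if (config$validation$design == "forward") {
    forward_split(drp, qc$genotypes, ratio = config$validation$ratio)
  } else {
    cv_plan(drp, k = config$validation$k,
            replicates = config$validation$replicates,
            seed = stage_seed(config$seed, "cv"))
  })

  metrics <- tick("evaluate", run_scenarios(
    drp, G, split, scenarios = config$scenarios,
    rbar_mode = config$model$rbar_mode,
    shared_residual = config$model$shared_residual,
    method = config$model$method, max_iter = config$model$max_iter,
    tol = config$model$tol))
  utils::write.table(metrics, file.path(outdir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary_df <- summarize_metrics(metrics)
  utils::write.table(summary_df, file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cfg_path <- file.path(outdir, "experiment_config.json")
  cfg_plain <- unclass(config)
  cfg_plain$sim <- unclass(cfg_plain$sim)
  jsonlite::write_json(cfg_plain, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  prov <- list(config_md5 = unname(tools::md5sum(cfg_path)),
               global_seed = config$seed,
               stage_seeds = list(simulate = stage_seed(config$seed, "simulate"),
                                  qc = stage_seed(config$seed, "qc"),
                                  cv = stage_seed(config$seed, "cv")),
               timings = timings,
               file_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(metrics = metrics, summary = summary_df,
                 qc_report = qc$report, grm_summary = grm_summary,
                 paths = outdir))
}
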