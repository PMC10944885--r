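#' Run configuration
#'
#' Reproducibility settings for [run_pipeline()]. Replicate-count defaults
#' follow the study's validation settings: 1,000 bootstrap resamples,
#' 1,000 VPC replicates, 1,000 NPDE replicates, 500 virtual patients per
#' exposure scenario.
#'
#' @param seed Global seed; per-stage child seeds are derived
#'   deterministically so stages can be rerun independently.
#' @param n_bootstrap,n_vpc,n_npde,n_sim Replicate counts (all >= 1).
#' @param control [fit_control()] for estimation stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_bootstrap = 1000, n_vpc = 1000,
                       n_npde = 1000, n_sim = 500, control = fit_control()) {
  counts <- c(n_bootstrap, n_vpc, n_npde, n_sim)
  if (any(counts < 1)) stop("replicate counts must be >= 1")
  structure(list(seed = as.integer(seed), n_bootstrap = n_bootstrap,
                 n_vpc = n_vpc, n_npde = n_npde, n_sim = n_sim,
                 control = control), class = "run_config")
}

stage_seed <- function(config, stage) {
  offsets <- c(generate = 11L, fit = 23L, select = 37L, gof = 41L,
               bootstrap = 53L, vpc = 67L, npde = 79L, nca = 83L,
               simulate = 97L)
  config$seed * 1000L + offsets[[stage]]
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config[setdiff(names(config), "control")], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order on a synthetic trial:
#' `generate` (synthetic dataset), `fit` (FOCE estimation of the final
#' model structure), `select` (stepwise covariate search from the base
#' model), `gof`, `bootstrap`, `vpc`, `npde` (diagnostics of the fit),
#' `nca` and `simulate` (steady-state covariate impact). Every artifact is
#' written under `out_dir` together with a JSON manifest carrying the
#' seed, configuration hash and package version; outputs are reproducible
#' given the seed.
#'
#' @param stages Character vector of stages to run (subset of the above).
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param design A [trial_design()].
#' @param truth The data-generating `poppk_model`.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(stages = c("generate", "fit", "gof", "vpc", "npde",
                                    "nca", "simulate"),
                         config = run_config(), out_dir = NULL,
                         design = trial_design(), truth = orin_final_model()) {
  all_stages <- c("generate", "fit", "select", "gof", "bootstrap", "vpc",
                  "npde", "nca", "simulate")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  needs_fit <- c("gof", "bootstrap", "vpc", "npde")
  if (any(needs_fit %in% stages) && !"fit" %in% stages)
    stop("stage dependency missing: ",
         paste(intersect(needs_fit, stages), collapse = ", "),
         " require(s) the 'fit' stage")
  if (any(c("fit", "select", "nca") %in% stages) && !"generate" %in% stages)
    stop("stage dependency missing: estimation/NCA stages require 'generate'")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- list()
  save_csv <- function(df, name) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  tictoc <- function(stage, expr) {
    t0 <- Sys.time()
    out <- expr
    message(sprintf("[%s] done in %.1fs (seed %d)", stage,
                    as.numeric(Sys.time() - t0, units = "secs"),
                    stage_seed(config, stage)))
    out
  }
  for (stage in stages) {
    sd <- stage_seed(config, stage)
    if (stage == "generate") {
      res$dataset <- tictoc(stage, generate_trial(design, truth, seed = sd))
      if (!is.null(out_dir))
        write_pk_dataset(res$dataset, file.path(out_dir, "trial.csv"))
    } else if (stage == "fit") {
      res$fit <- tictoc(stage, fit_poppk(truth, res$dataset,
                                         control = config$control))
      save_csv(res$fit$estimates, "fit_estimates")
    } else if (stage == "select") {
      base <- truth
      base$effects <- NULL
      base_fit <- fit_poppk(base, res$dataset,
                            control = fit_control(se = FALSE))
      screen <- covariate_prescreen(
        res$dataset$subjects[covariate_columns(res$dataset)])
      res$selection <- tictoc(stage, run_stepwise(
        base_fit, res$dataset, screen$candidates))
      save_csv(res$selection$trace, "stepwise_trace")
    } else if (stage == "gof") {
      res$gof <- tictoc(stage, gof_table(res$fit, res$dataset))
      save_csv(res$gof, "gof")
    } else if (stage == "bootstrap") {
      res$bootstrap <- tictoc(stage, bootstrap_poppk(
        res$fit, res$dataset, n = config$n_bootstrap, seed = sd))
      save_csv(res$bootstrap$summary, "bootstrap")
    } else if (stage == "vpc") {
      res$vpc <- tictoc(stage, vpc(res$fit$model, res$dataset,
                                   nsim = config$n_vpc, seed = sd))
      save_csv(res$vpc$table, "vpc")
    } else if (stage == "npde") {
      res$npde <- tictoc(stage, npde(res$fit$model, res$dataset,
                                     nsim = config$n_npde, seed = sd))
      save_csv(res$npde$npde, "npde")
    } else if (stage == "nca") {
      res$nca <- tictoc(stage, nca_dataset(res$dataset, "single"))
      save_csv(res$nca, "nca")
    } else if (stage == "simulate") {
      res$exposure <- tictoc(stage, simulate_covariate_effects(
        truth, n = config$n_sim, seed = sd))
      save_csv(res$exposure$table, "exposure_fold_changes")
    }
  }
  manifest <- list(stages = stages, seed = config$seed,
                   stage_seeds = vapply(stages, function(s) stage_seed(config, s),
                                        integer(1)),
                   config_hash = config_hash(config),
                   replicates = list(bootstrap = config$n_bootstrap,
                                     vpc = config$n_vpc, npde = config$n_npde,
                                     simulation = config$n_sim),
                   package_version = as.character(utils::packageVersion("orinpk")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
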