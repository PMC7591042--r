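#' Pipeline run configuration
#'
#' Bundles every setting of the end-to-end workflow: task structure, group
#' specifications, candidate models, MCMC, model-comparison, prediction and
#' optimality-grid settings, plus the master seed that is fanned out
#' deterministically to every stage. Round-trips losslessly through JSON
#' via [write_config()] / [read_config()].
#'
#' @param n_trials,reversal_trial,p_reward Task settings (see
#'   [build_schedule()]).
#' @param group_specs List of [group_spec()] objects (default
#'   [default_group_specs()]).
#' @param models Candidate models fit to every group.
#' @param mcmc An [mcmc_config()]; the default uses reduced desk-scale
#'   settings (2 chains x 1,000 draws after 750 warmup).
#' @param n_bootstrap Bayesian-bootstrap replicates for model weights.
#' @param n_onestep Draws used in one-step-ahead prediction (default: all).
#' @param optimal_grid_points,optimal_n_sims Optimality-grid settings
#'   (`NULL` uses the per-model defaults of
#'   [optimal_learning_params()]).
#' @param seed Master seed.
#' @return A list of class `prl_config`.
#' @export
prl_config <- function(n_trials = 80L, reversal_trial = 41L,
                       p_reward = 0.8,
                       group_specs = default_group_specs(),
                       models = c("CU", "RP", "EWA_DL"),
                       mcmc = mcmc_config(chains = 2L, iter = 1000L,
                                          warmup = 750L),
                       n_bootstrap = 10000L, n_onestep = NULL,
                       optimal_grid_points = NULL, optimal_n_sims = NULL,
                       seed = 1L) {
  structure(list(n_trials = as.integer(n_trials),
                 reversal_trial = as.integer(reversal_trial),
                 p_reward = p_reward, group_specs = group_specs,
                 models = models, mcmc = mcmc,
                 n_bootstrap = as.integer(n_bootstrap),
                 n_onestep = n_onestep,
                 optimal_grid_points = optimal_grid_points,
                 optimal_n_sims = optimal_n_sims,
                 seed = as.integer(seed)),
            class = "prl_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config A [prl_config()].
#' @param path JSON file path.
#' @return `path` (write) or the reconstructed `prl_config` (read).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$mcmc <- unclass(x$mcmc)
  x$group_specs <- lapply(x$group_specs, function(s) {
    s <- unclass(s)
    s$means <- as.list(s$means)
    s$sds <- as.list(s$sds)
    s
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(seq_len(length(x$group_specs$diagnosis)), function(i) NULL)
  gs <- x$group_specs
  specs <- if (is.data.frame(gs)) {
    lapply(seq_len(nrow(gs)), function(i) {
      group_spec(gs$diagnosis[i], gs$age_group[i], gs$model_id[i],
                 unlist(gs$means[i, , drop = TRUE]),
                 unlist(gs$sds[i, , drop = TRUE]), gs$n_subjects[i])
    })
  } else {
    lapply(gs, function(s) {
      group_spec(s$diagnosis, s$age_group, s$model_id, unlist(s$means),
                 unlist(s$sds), s$n_subjects)
    })
  }
  prl_config(n_trials = x$n_trials, reversal_trial = x$reversal_trial,
             p_reward = x$p_reward, group_specs = specs,
             models = x$models,
             mcmc = do.call(mcmc_config, as.list(x$mcmc)),
             n_bootstrap = x$n_bootstrap,
             n_onestep = x$n_onestep,
             optimal_grid_points = x$optimal_grid_points,
             optimal_n_sims = x$optimal_n_sims, seed = x$seed)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(dir, config, stage, files, errors = list()) {
  manifest <- list(stage = stage, config_hash = config_hash(config),
                   seed = config$seed, files = files,
                   errors = errors,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest,
                       file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a cohort to disk
#'
#' Builds the schedule and synthetic cohort described by the config and
#' writes `schedule.csv`, `cohort.csv`, `ground_truth.csv` and a manifest
#' (config hash, seeds, file list) to `out_dir`, creating it if needed.
#' Rerunning with the same config reproduces the files exactly.
#'
#' @param config A [prl_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the generated `prl_cohort`.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- build_schedule(config$n_trials, config$reversal_trial,
                             config$p_reward,
                             seed = derive_seed(config$seed, 0L))
  cohort <- generate_cohort(config$group_specs, schedule,
                            seed = derive_seed(config$seed, 1L))
  write.csv(as.data.frame(schedule), file.path(out_dir, "schedule.csv"),
            row.names = FALSE)
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"),
                   file.path(out_dir, "ground_truth.csv"))
  write_manifest(out_dir, config, "simulate",
                 c("schedule.csv", "cohort.csv", "ground_truth.csv"))
  message(sprintf("simulated %d subjects in %d group(s) -> %s",
                  length(cohort$subjects), length(config$group_specs),
                  out_dir))
  invisible(cohort)
}

#' Run the full analysis pipeline on a cohort CSV
#'
#' Orchestrates the in-scope analysis stages: behavioral metrics, per-group
#' hierarchical fits of every candidate model, pseudo-BMA model weights per
#' group, one-step-ahead prediction under each group's winning model, and
#' optimality-grid simulations for each model. Every stage writes a CSV;
#' stage failures are recorded in the manifest and downstream stages for
#' the affected group are skipped rather than aborting the run.
#'
#' @param config A [prl_config()].
#' @param cohort_csv Trial-level cohort CSV (see [write_cohort_csv()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the computed tables.
#' @export
run_analyze <- function(config, cohort_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_cohort_csv(cohort_csv)
  schedule_seed <- derive_seed(config$seed, 0L)
  errors <- list()
  files <- character()

  metrics <- behavior_summary(cohort)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write.csv(behavior_group_summary(metrics),
            file.path(out_dir, "metrics_groups.csv"), row.names = FALSE)
  files <- c(files, "metrics.csv", "metrics_groups.csv")

  cells <- unique(metrics[, c("diagnosis", "age_group")])
  weight_rows <- list()
  pred_rows <- list()
  for (i in seq_len(nrow(cells))) {
    dg <- cells$diagnosis[i]
    ag <- cells$age_group[i]
    subjects <- cohort_subset(cohort, dg, ag)
    lls <- list()
    fits <- list()
    for (m in config$models) {
      fit <- tryCatch(
        fit_group(subjects, m,
                  modifyList(config$mcmc,
                             list(seed = derive_seed(config$seed,
                                                     10L * i + match(m, config$models))))),
        error = function(e) e)
      if (inherits(fit, "error")) {
        errors[[sprintf("fit:%s_%s:%s", dg, ag, m)]] <- conditionMessage(fit)
        next
      }
      fits[[m]] <- fit
      lls[[m]] <- pointwise_loglik(fit, subjects)
    }
    if (length(lls) < 2) {
      errors[[sprintf("weights:%s_%s", dg, ag)]] <-
        "fewer than two successful fits; model comparison skipped"
      next
    }
    wt <- model_weights(lls, n_bootstrap = config$n_bootstrap,
                        seed = derive_seed(config$seed, 500L + i))
    weight_rows[[i]] <- cbind(diagnosis = dg, age_group = ag,
                              as.data.frame(wt))
    win <- winning_model(wt)
    for (s in subjects) {
      pr <- one_step_ahead(fits[[win]], s, n_iter = config$n_onestep,
                           seed = derive_seed(config$seed, 900L + i))
      pred_rows[[length(pred_rows) + 1L]] <-
        data.frame(subject_id = s$subject_id, diagnosis = dg,
                   age_group = ag, model = win,
                   predictive_accuracy = pr$accuracy,
                   p_value = pr$p_value, stringsAsFactors = FALSE)
    }
  }
  weights <- do.call(rbind, weight_rows)
  if (!is.null(weights)) {
    write.csv(weights, file.path(out_dir, "model_weights.csv"),
              row.names = FALSE)
    files <- c(files, "model_weights.csv")
  }
  preds <- do.call(rbind, pred_rows)
  if (!is.null(preds)) {
    write.csv(preds, file.path(out_dir, "predictions.csv"),
              row.names = FALSE)
    files <- c(files, "predictions.csv")
  }

  schedule <- build_schedule(config$n_trials, config$reversal_trial,
                             config$p_reward, seed = schedule_seed)
  grids <- list()
  for (m in intersect(config$models, c("CU", "RP", "EWA_DL", "RW"))) {
    g <- optimal_learning_params(m, schedule,
                                 grid_points = config$optimal_grid_points,
                                 n_sims = config$optimal_n_sims,
                                 seed = derive_seed(config$seed, 700L +
                                                      match(m, config$models)))
    grids[[m]] <- g
    fn <- sprintf("optimal_%s.csv", m)
    write.csv(g$surface, file.path(out_dir, fn), row.names = FALSE)
    files <- c(files, fn)
  }

  write_manifest(out_dir, config, "analyze", files, errors)
  if (length(errors) > 0) {
    warning(sprintf("%d stage failure(s) recorded in the manifest",
                    length(errors)), call. = FALSE)
  }
  invisible(list(metrics = metrics, weights = weights,
                 predictions = preds, grids = grids, errors = errors))
}
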