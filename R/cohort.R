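#' Construct a subject record
#'
#' Bundles one subject's trial-level choice/outcome sequence with group
#' labels. `trials` must be a data.frame with columns `trial` (contiguous
#' from 1), `choice` (`"A"`/`"B"`), `outcome` (+1/-1), `correct_stim`
#' (`"A"`/`"B"`) and `phase` (`"acquisition"`/`"reversal"`); exactly one
#' correct-stimulus flip is allowed, at the acquisition/reversal boundary.
#'
#' @param subject_id Character id.
#' @param diagnosis `"ASD"` or `"TD"`.
#' @param age_group `"children"`, `"adolescents"` or `"adults"`.
#' @param trials Trial-level data.frame as described above.
#' @return An object of class `prl_subject`.
#' @export
prl_subject <- function(subject_id, diagnosis, age_group, trials) {
  diagnosis <- match.arg(diagnosis, c("ASD", "TD"))
  age_group <- match.arg(age_group, c("children", "adolescents", "adults"))
  obj <- structure(list(subject_id = as.character(subject_id),
                        diagnosis = diagnosis, age_group = age_group,
                        trials = trials),
                   class = "prl_subject")
  validate_subject(obj)
  obj
}

#' Validate a subject record's invariants
#'
#' Checks trial contiguity, outcome coding, phase labeling and that the
#' correct stimulus flips exactly once, at the phase boundary.
#'
#' @param x A [prl_subject()] object.
#' @return `x`, invisibly; errors describe the offending row.
#' @export
validate_subject <- function(x) {
  tr <- x$trials
  need <- c("trial", "choice", "outcome", "correct_stim", "phase")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0) {
    stop(sprintf("subject %s: missing trial columns: %s", x$subject_id,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(tr)
  if (!identical(as.integer(tr$trial), seq_len(n))) {
    stop(sprintf("subject %s: trials must be contiguous from 1 to %d",
                 x$subject_id, n), call. = FALSE)
  }
  bad <- which(!(tr$outcome %in% c(-1, 1)))
  if (length(bad) > 0) {
    stop(sprintf("subject %s: invalid outcome at trial %d", x$subject_id,
                 bad[1]), call. = FALSE)
  }
  bad <- which(!(tr$choice %in% c("A", "B")) |
                 !(tr$correct_stim %in% c("A", "B")))
  if (length(bad) > 0) {
    stop(sprintf("subject %s: invalid stimulus label at trial %d",
                 x$subject_id, bad[1]), call. = FALSE)
  }
  flips <- which(tr$correct_stim[-1] != tr$correct_stim[-n]) + 1L
  if (length(flips) != 1L) {
    stop(sprintf("subject %s: expected exactly one correct-stimulus flip, found %d",
                 x$subject_id, length(flips)), call. = FALSE)
  }
  if (!identical(tr$phase, ifelse(seq_len(n) >= flips, "reversal",
                                  "acquisition"))) {
    stop(sprintf("subject %s: phase labels inconsistent with the reversal at trial %d",
                 x$subject_id, flips), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.prl_subject <- function(x, ...) {
  cat(sprintf("PRL subject %s (%s, %s): %d trials\n", x$subject_id,
              x$diagnosis, x$age_group, nrow(x$trials)))
  invisible(x)
}

#' Simulate one agent on a task schedule
#'
#' Plays a learning model forward through the schedule: the first choice is
#' sampled from the softmax at the initial state (so only the indifference
#' point biases it), that choice defines the acquisition-phase correct
#' stimulus, and thereafter each trial samples a choice from the current
#' choice probability, receives anti-correlated feedback from the schedule,
#' and updates the model state.
#'
#' @param model_id One of [prl_models()].
#' @param params Named parameter vector (see [param_bounds()]).
#' @param schedule A [build_schedule()] object.
#' @param seed RNG seed; the same seed reproduces the agent exactly.
#' @param subject_id,diagnosis,age_group Labels attached to the result.
#' @return A [prl_subject()] with an attribute `"params"` holding the
#'   generating parameters and `"model_id"` the generating model.
#' @export
simulate_agent <- function(model_id, params, schedule, seed = 1L,
                           subject_id = "sim1", diagnosis = "TD",
                           age_group = "adults") {
  model_id <- match.arg(model_id, prl_models())
  stopifnot(inherits(schedule, "prl_schedule"))
  p <- canonical_params(model_id, params)
  set.seed(as.integer(seed))
  sim <- cpp_simulate_agent(model_code(model_id), unname(p),
                            schedule$scheduled_outcome,
                            schedule$reversal_trial)
  n <- schedule$n_trials
  tr <- data.frame(
    trial = seq_len(n),
    choice = c("A", "B")[sim$choice + 1L],
    outcome = as.numeric(sim$outcome),
    correct_stim = c("A", "B")[sim$correct + 1L],
    phase = ifelse(seq_len(n) >= schedule$reversal_trial, "reversal",
                   "acquisition"),
    stringsAsFactors = FALSE)
  out <- prl_subject(subject_id, diagnosis, age_group, tr)
  attr(out, "model_id") <- model_id
  attr(out, "params") <- p
  out
}

#' Specify one synthetic group
#'
#' Describes a diagnosis-by-age cell of a synthetic cohort: its generative
#' model and the mean/SD of each parameter. Individual parameters are drawn
#' from normals truncated to each parameter's support.
#'
#' @param diagnosis `"ASD"` or `"TD"`.
#' @param age_group `"children"`, `"adolescents"` or `"adults"`.
#' @param model_id Generative model.
#' @param means,sds Named numeric vectors over the model's parameters.
#' @param n_subjects Number of subjects in the group.
#' @return An object of class `prl_group_spec`.
#' @export
group_spec <- function(diagnosis, age_group, model_id, means, sds,
                       n_subjects) {
  model_id <- match.arg(model_id, prl_models())
  means <- canonical_params(model_id, means)
  b <- param_bounds(model_id)
  sds <- sds[b$param]
  if (any(is.na(sds)) || any(sds < 0)) {
    stop("sds must be named, nonnegative, and cover every model parameter",
         call. = FALSE)
  }
  structure(list(diagnosis = match.arg(diagnosis, c("ASD", "TD")),
                 age_group = match.arg(age_group,
                                       c("children", "adolescents", "adults")),
                 model_id = model_id, means = means,
                 sds = stats::setNames(as.numeric(sds), b$param),
                 n_subjects = as.integer(n_subjects)),
            class = "prl_group_spec")
}

#' Default six-group cohort specification
#'
#' The generator's default study design: six groups (ASD/TD crossed with
#' children, adolescents and adults), each generated from the learning model
#' that best describes that age group (children: counterfactual update;
#' adolescents: reward-punishment; adults: EWA-DL), with group-level
#' parameter means and SDs matching the fitted estimates for each cell and
#' the corresponding published group sizes.
#'
#' @param n_subjects Optional single count overriding every group's size
#'   (useful for reduced test cohorts).
#' @return A list of six [group_spec()] objects.
#' @export
default_group_specs <- function(n_subjects = NULL) {
  specs <- list(
    group_spec("ASD", "children", "CU",
               c(eta = 0.258, beta = 0.979, alpha = -0.014),
               c(eta = 0.126, beta = 0.783, alpha = 0.319), 81L),
    group_spec("TD", "children", "CU",
               c(eta = 0.193, beta = 1.202, alpha = -0.042),
               c(eta = 0.087, beta = 0.892, alpha = 0.153), 64L),
    group_spec("ASD", "adolescents", "RP",
               c(eta_rew = 0.368, eta_pun = 0.336, beta = 1.494,
                 alpha = -0.032),
               c(eta_rew = 0.169, eta_pun = 0.098, beta = 0.897,
                 alpha = 0.255), 114L),
    group_spec("TD", "adolescents", "RP",
               c(eta_rew = 0.443, eta_pun = 0.311, beta = 2.535,
                 alpha = -0.031),
               c(eta_rew = 0.223, eta_pun = 0.116, beta = 1.108,
                 alpha = 0.161), 90L),
    group_spec("ASD", "adults", "EWA_DL",
               c(phi = 0.521, rho = 0.379, beta = 1.231, alpha = -0.052),
               c(phi = 0.185, rho = 0.268, beta = 0.742, alpha = 0.308),
               126L),
    group_spec("TD", "adults", "EWA_DL",
               c(phi = 0.587, rho = 0.308, beta = 1.290, alpha = 0.040),
               c(phi = 0.101, rho = 0.200, beta = 0.763, alpha = 0.344),
               97L))
  if (!is.null(n_subjects)) {
    specs <- lapply(specs, function(s) {
      s$n_subjects <- as.integer(n_subjects)
      s
    })
  }
  specs
}

#' Generate a synthetic cohort
#'
#' For each group spec, draws per-subject parameters from truncated normals
#' at the group means/SDs and simulates one agent per subject on the shared
#' schedule. Parameter draws and task feedback use separate RNG streams
#' derived from the master seed, so the two noise sources can be varied
#' independently. Ground-truth parameters are stored with the cohort for
#' recovery testing.
#'
#' @param specs List of [group_spec()] objects.
#' @param schedule A [build_schedule()] object.
#' @param seed Master seed.
#' @return An object of class `prl_cohort`: list with `subjects` (list of
#'   [prl_subject()]) and `ground_truth` (data.frame of subject ids, group
#'   labels, generating model and parameters).
#' @export
generate_cohort <- function(specs, schedule, seed = 1L) {
  if (inherits(specs, "prl_group_spec")) specs <- list(specs)
  if (length(specs) == 0) stop("specs must be nonempty", call. = FALSE)
  subjects <- list()
  truth <- list()
  sidx <- 0L
  for (gi in seq_along(specs)) {
    spec <- specs[[gi]]
    if (spec$n_subjects == 0L) next
    b <- param_bounds(spec$model_id)
    # stream 1: parameter draws for this group
    set.seed(derive_seed(seed, 2L * gi - 1L))
    draws <- sapply(seq_len(nrow(b)), function(k) {
      rtruncnorm(spec$n_subjects, spec$means[k], spec$sds[k],
                 b$lower[k], b$upper[k])
    })
    draws <- matrix(draws, nrow = spec$n_subjects,
                    dimnames = list(NULL, b$param))
    # stream 2: task feedback / choice noise
    feed_seed <- derive_seed(seed, 2L * gi)
    for (i in seq_len(spec$n_subjects)) {
      sidx <- sidx + 1L
      id <- sprintf("%s_%s_%03d", spec$diagnosis, spec$age_group, i)
      sub <- simulate_agent(spec$model_id, draws[i, ], schedule,
                            seed = derive_seed(feed_seed, i),
                            subject_id = id, diagnosis = spec$diagnosis,
                            age_group = spec$age_group)
      subjects[[sidx]] <- sub
      truth[[sidx]] <- data.frame(subject_id = id,
                                  diagnosis = spec$diagnosis,
                                  age_group = spec$age_group,
                                  model_id = spec$model_id,
                                  param = b$param,
                                  value = unname(draws[i, ]),
                                  stringsAsFactors = FALSE)
    }
  }
  structure(list(subjects = subjects,
                 ground_truth = do.call(rbind, truth),
                 seed = as.integer(seed)),
            class = "prl_cohort")
}

#' @export
print.prl_cohort <- function(x, ...) {
  cat(sprintf("PRL cohort: %d subjects\n", length(x$subjects)))
  invisible(x)
}

#' Simulate a model-recovery cohort
#'
#' Generates subjects from one model with parameters drawn uniformly over
#' each parameter's support, for use in model-recovery analyses where the
#' generating model's identity must be re-identified by fitting.
#'
#' @param model_id Generating model.
#' @param n_subjects Number of synthetic participants (default 40).
#' @param schedule A [build_schedule()] object.
#' @param seed Master seed.
#' @return A `prl_cohort` with ground truth attached.
#' @export
recovery_set <- function(model_id, n_subjects = 40L, schedule, seed = 1L) {
  model_id <- match.arg(model_id, prl_models())
  b <- param_bounds(model_id)
  subjects <- list()
  truth <- list()
  set.seed(derive_seed(seed, 1L))
  draws <- sapply(seq_len(nrow(b)), function(k) {
    runif(n_subjects, b$lower[k], b$upper[k])
  })
  draws <- matrix(draws, nrow = n_subjects,
                  dimnames = list(NULL, b$param))
  feed_seed <- derive_seed(seed, 2L)
  for (i in seq_len(n_subjects)) {
    id <- sprintf("rec_%s_%03d", model_id, i)
    subjects[[i]] <- simulate_agent(model_id, draws[i, ], schedule,
                                    seed = derive_seed(feed_seed, i),
                                    subject_id = id)
    truth[[i]] <- data.frame(subject_id = id, diagnosis = "TD",
                             age_group = "adults", model_id = model_id,
                             param = b$param, value = unname(draws[i, ]),
                             stringsAsFactors = FALSE)
  }
  structure(list(subjects = subjects, ground_truth = do.call(rbind, truth),
                 seed = as.integer(seed)),
            class = "prl_cohort")
}

#' Write / read a cohort as trial-level CSV
#'
#' The cohort is serialized as one row per trial with columns `subject_id`,
#' `diagnosis`, `age_group`, `trial`, `phase`, `choice`, `outcome`,
#' `correct_stim`; ground truth goes to a sidecar CSV in long format
#' (`subject_id`, `model_id`, `param`, `value`).
#'
#' @param cohort A `prl_cohort`.
#' @param path Trial-level CSV path.
#' @param truth_path Optional sidecar CSV path for ground truth.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, truth_path = NULL) {
  rows <- lapply(cohort$subjects, function(s) {
    cbind(data.frame(subject_id = s$subject_id, diagnosis = s$diagnosis,
                     age_group = s$age_group, stringsAsFactors = FALSE),
          s$trials[, c("trial", "phase", "choice", "outcome",
                       "correct_stim")])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (!is.null(truth_path) && !is.null(cohort$ground_truth)) {
    write.csv(cohort$ground_truth, truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param validate Check every subject's invariants on read.
#' @export
read_cohort_csv <- function(path, truth_path = NULL, validate = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "diagnosis", "age_group", "trial", "phase",
            "choice", "outcome", "correct_stim")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("cohort CSV missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  subjects <- lapply(split(df, factor(df$subject_id,
                                      levels = unique(df$subject_id))),
                     function(d) {
    d <- d[order(d$trial), ]
    s <- structure(list(subject_id = d$subject_id[1],
                        diagnosis = d$diagnosis[1],
                        age_group = d$age_group[1],
                        trials = data.frame(
                          trial = as.integer(d$trial), choice = d$choice,
                          outcome = as.numeric(d$outcome),
                          correct_stim = d$correct_stim, phase = d$phase,
                          stringsAsFactors = FALSE, row.names = NULL)),
                   class = "prl_subject")
    if (validate) validate_subject(s)
    s
  })
  names(subjects) <- NULL
  truth <- if (!is.null(truth_path)) read.csv(truth_path,
                                              stringsAsFactors = FALSE)
           else NULL
  structure(list(subjects = subjects, ground_truth = truth, seed = NA_integer_),
            class = "prl_cohort")
}

# convenience: subset a cohort by group labels
cohort_subset <- function(cohort, diagnosis = NULL, age_group = NULL) {
  keep <- vapply(cohort$subjects, function(s) {
    (is.null(diagnosis) || s$diagnosis == diagnosis) &&
      (is.null(age_group) || s$age_group == age_group)
  }, logical(1))
  cohort$subjects[keep]
}
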