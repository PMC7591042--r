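#' Choice accuracy overall and by phase
#'
#' A trial is correct when the chosen stimulus equals the currently
#' usually-rewarded stimulus (which flips at the reversal).
#'
#' @param data A [prl_subject()] object.
#' @return Named numeric: `overall`, `acquisition`, `reversal`.
#' @export
accuracy_by_phase <- function(data) {
  tr <- data$trials
  correct <- tr$choice == tr$correct_stim
  acq <- tr$phase == "acquisition"
  c(overall = mean(correct),
    acquisition = mean(correct[acq]),
    reversal = mean(correct[!acq]))
}

#' Perseverative errors as a proportion of reversal-phase trials
#'
#' An error trial is a reversal-phase choice of the pre-reversal correct
#' stimulus. Trials count as perseverative when they belong to a run of two
#' or more consecutive such errors; isolated errors do not. By default the
#' count ignores the feedback actually received on each error trial
#' (misleading rewards included); set `require_negative_feedback = TRUE` to
#' count runs only while negative feedback persists.
#'
#' @param data A [prl_subject()] object.
#' @param require_negative_feedback Restrict runs to negatively-reinforced
#'   errors (default `FALSE`).
#' @return Proportion of reversal-phase trials in perseverative runs.
#' @export
perseverative_errors <- function(data, require_negative_feedback = FALSE) {
  tr <- data$trials
  rev <- tr[tr$phase == "reversal", ]
  if (nrow(rev) == 0) return(NA_real_)
  prev_correct <- tr$correct_stim[tr$phase == "acquisition"][1]
  err <- rev$choice == prev_correct
  if (require_negative_feedback) err <- err & rev$outcome < 0
  runs <- rle(err)
  persev <- sum(runs$lengths[runs$values & runs$lengths >= 2])
  persev / nrow(rev)
}

#' Win-stay and lose-shift proportions
#'
#' `win_stay()` is the proportion of rewarded trials (with a successor) on
#' which the next choice repeats the current one; `lose_shift()` is the
#' proportion of punished trials (with a successor) on which the next
#' choice changes. Final-trial outcomes have no successor and are excluded
#' from the denominators; an empty denominator yields `NA`, never 0.
#'
#' @param data A [prl_subject()] object.
#' @return A proportion in `[0, 1]`, or `NA` if no eligible trials exist.
#' @export
win_stay <- function(data) {
  tr <- data$trials
  n <- nrow(tr)
  if (n < 2) return(NA_real_)
  won <- tr$outcome[-n] > 0
  if (!any(won)) return(NA_real_)
  stayed <- tr$choice[-1] == tr$choice[-n]
  mean(stayed[won])
}

#' @rdname win_stay
#' @export
lose_shift <- function(data) {
  tr <- data$trials
  n <- nrow(tr)
  if (n < 2) return(NA_real_)
  lost <- tr$outcome[-n] < 0
  if (!any(lost)) return(NA_real_)
  shifted <- tr$choice[-1] != tr$choice[-n]
  mean(shifted[lost])
}

#' Learning criterion per phase
#'
#' Operationalizes "evidence of learning" as a one-sided exact binomial
#' test of phase accuracy against chance (0.5) at the given level; a phase
#' passes when the test rejects.
#'
#' @param data A [prl_subject()] object.
#' @param level Significance level (default 0.05).
#' @return Named logical: `acquisition`, `reversal`.
#' @export
learning_criterion <- function(data, level = 0.05) {
  tr <- data$trials
  pass_phase <- function(phase) {
    sub <- tr[tr$phase == phase, ]
    k <- sum(sub$choice == sub$correct_stim)
    binom.test(k, nrow(sub), p = 0.5, alternative = "greater")$p.value < level
  }
  c(acquisition = pass_phase("acquisition"),
    reversal = pass_phase("reversal"))
}

#' Behavioral summary for one subject or a cohort
#'
#' One row per subject with accuracy (overall/acquisition/reversal),
#' perseverative errors, win-stay, lose-shift, and the per-phase learning
#' criterion.
#'
#' @param x A [prl_subject()], a `prl_cohort`, or a list of subjects.
#' @param ... Passed to [perseverative_errors()].
#' @return A data.frame, one row per subject.
#' @export
behavior_summary <- function(x, ...) {
  subjects <- if (inherits(x, "prl_subject")) list(x)
              else if (inherits(x, "prl_cohort")) x$subjects
              else x
  rows <- lapply(subjects, function(s) {
    acc <- accuracy_by_phase(s)
    lc <- learning_criterion(s)
    data.frame(subject_id = s$subject_id, diagnosis = s$diagnosis,
               age_group = s$age_group,
               accuracy_overall = acc[["overall"]],
               accuracy_acquisition = acc[["acquisition"]],
               accuracy_reversal = acc[["reversal"]],
               perseverative_errors = perseverative_errors(s, ...),
               win_stay = win_stay(s), lose_shift = lose_shift(s),
               learning_pass_acquisition = lc[["acquisition"]],
               learning_pass_reversal = lc[["reversal"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group means and SDs of the behavioral measures
#'
#' @param summary_df Output of [behavior_summary()].
#' @return A data.frame with one row per diagnosis-by-age cell and
#'   mean/SD columns per measure.
#' @export
behavior_group_summary <- function(summary_df) {
  measures <- c("accuracy_overall", "accuracy_acquisition",
                "accuracy_reversal", "perseverative_errors", "win_stay",
                "lose_shift")
  cells <- unique(summary_df[, c("diagnosis", "age_group")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- summary_df[summary_df$diagnosis == cells$diagnosis[i] &
                        summary_df$age_group == cells$age_group[i], ]
    stats <- unlist(lapply(measures, function(m) {
      v <- sub[[m]]
      stats::setNames(c(mean(v, na.rm = TRUE), sd(v, na.rm = TRUE)),
                      paste0(m, c("_mean", "_sd")))
    }))
    cbind(cells[i, , drop = FALSE], n = nrow(sub), as.data.frame(t(stats)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
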