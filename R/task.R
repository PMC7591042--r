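#' Build a fixed probabilistic feedback schedule
#'
#' Constructs the pseudorandom feedback plan of the reversal-learning task:
#' `n_trials` trials split into an acquisition phase (trials
#' `1..reversal_trial-1`) and a reversal phase (trials
#' `reversal_trial..n_trials`). Within each phase, exactly
#' `p_reward * phase_length` trials carry a scheduled reward (+1) for the
#' currently-correct stimulus and the rest a scheduled punishment (-1).
#' Punishments are placed uniformly at random within each phase subject to a
#' run-length cap of two consecutive punishments, so probabilistic
#' "misleading" feedback never mimics a reversal.
#'
#' @param n_trials Number of trials (default 80).
#' @param reversal_trial 1-based index of the first reversal-phase trial
#'   (default 41).
#' @param p_reward Probability that the currently-correct choice is rewarded
#'   (default 0.8). `p_reward * phase_length` must be an integer for each
#'   phase.
#' @param seed RNG seed; the same seed always yields the same schedule.
#' @return An object of class `prl_schedule`: a list with `n_trials`,
#'   `reversal_trial`, `p_reward`, `seed` and `scheduled_outcome` (an
#'   integer vector of +1/-1, the outcome delivered if the currently-correct
#'   stimulus is chosen).
#' @examples
#' sched <- build_schedule(seed = 1)
#' table(sched$scheduled_outcome[1:40])  # 32 rewards, 8 punishments
#' @export
build_schedule <- function(n_trials = 80L, reversal_trial = 41L,
                           p_reward = 0.8, seed = 1L) {
  n_trials <- as.integer(n_trials)
  reversal_trial <- as.integer(reversal_trial)
  if (n_trials < 2L) stop("n_trials must be at least 2", call. = FALSE)
  if (reversal_trial <= 1L || reversal_trial > n_trials) {
    stop("reversal_trial must satisfy 1 < reversal_trial <= n_trials",
         call. = FALSE)
  }
  if (p_reward < 0 || p_reward > 1) stop("p_reward must be in [0, 1]",
                                         call. = FALSE)
  phase_len <- c(reversal_trial - 1L, n_trials - reversal_trial + 1L)
  n_rew <- p_reward * phase_len
  if (any(abs(n_rew - round(n_rew)) > 1e-8)) {
    stop(sprintf(paste0("p_reward * phase length must be an integer; got ",
                        "%.3f and %.3f rewards for phases of %d and %d ",
                        "trials"),
                 n_rew[1], n_rew[2], phase_len[1], phase_len[2]),
         call. = FALSE)
  }
  n_rew <- as.integer(round(n_rew))

  set.seed(as.integer(seed))
  place_phase <- function(len, rewards) {
    n_pun <- len - rewards
    if (n_pun == 0L) return(rep(1L, len))
    repeat {
      out <- rep(1L, len)
      out[sample.int(len, n_pun)] <- -1L
      runs <- rle(out)
      if (max(runs$lengths[runs$values == -1L]) <= 2L) return(out)
    }
  }
  sched <- c(place_phase(phase_len[1], n_rew[1]),
             place_phase(phase_len[2], n_rew[2]))
  structure(list(n_trials = n_trials, reversal_trial = reversal_trial,
                 p_reward = p_reward, seed = as.integer(seed),
                 scheduled_outcome = sched),
            class = "prl_schedule")
}

#' @export
print.prl_schedule <- function(x, ...) {
  cat(sprintf("PRL schedule: %d trials, reversal at trial %d, p_reward %.2f, seed %d\n",
              x$n_trials, x$reversal_trial, x$p_reward, x$seed))
  invisible(x)
}

#' @export
as.data.frame.prl_schedule <- function(x, ...) {
  data.frame(trial = seq_len(x$n_trials),
             phase = ifelse(seq_len(x$n_trials) >= x$reversal_trial,
                            "reversal", "acquisition"),
             scheduled_outcome = x$scheduled_outcome,
             stringsAsFactors = FALSE)
}

check_stim <- function(x, what = "stimulus") {
  if (!is.character(x) || length(x) != 1L || !(x %in% c("A", "B"))) {
    stop(sprintf("%s must be \"A\" or \"B\"", what), call. = FALSE)
  }
  x
}

#' Deliver the outcome for a choice under a schedule
#'
#' The currently-correct stimulus receives the scheduled outcome; the other
#' stimulus receives its negation (the two stimuli are anti-correlated: when
#' one is correct, the other is incorrect).
#'
#' @param schedule A [build_schedule()] object.
#' @param trial 1-based trial index.
#' @param choice Chosen stimulus, `"A"` or `"B"`.
#' @param correct_stim Currently usually-rewarded stimulus, `"A"` or `"B"`.
#' @return `+1` or `-1`.
#' @export
deliver_outcome <- function(schedule, trial, choice, correct_stim) {
  stopifnot(inherits(schedule, "prl_schedule"))
  trial <- as.integer(trial)
  if (trial < 1L || trial > schedule$n_trials) {
    stop("trial outside schedule", call. = FALSE)
  }
  check_stim(choice, "choice")
  check_stim(correct_stim, "correct_stim")
  s <- schedule$scheduled_outcome[trial]
  if (choice == correct_stim) s else -s
}

#' Assign the correct stimulus from the first choice
#'
#' The stimulus chosen on trial 1 is defined as correct for the acquisition
#' phase; after the reversal the other stimulus becomes the usually-rewarded
#' one.
#'
#' @param first_choice `"A"` or `"B"`.
#' @return A list with elements `acquisition` and `reversal`.
#' @export
assign_correct_stimulus <- function(first_choice) {
  check_stim(first_choice, "first_choice")
  list(acquisition = first_choice,
       reversal = if (first_choice == "A") "B" else "A")
}
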