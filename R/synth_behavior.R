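#' Parameters for the synthetic reversal-learning behavior generator
#'
#' Defaults emulate the task conditions of the study: daily sessions of
#' ~40 trials, an 80%-correct acquisition criterion after which the rewarded
#' arm reverses without a cue, trial latencies shortening from ~71 s early to
#' ~28 s late in learning, anticipatory licking concentrated in the
#' pre-outcome zone (280-320 cm), and a lose-shift mechanism in which the
#' probability of switching arms after an unrewarded trial is a logistic
#' function of the simulated acetylcholine response amplitude on that trial.
#'
#' @param trials_per_session trials per daily session (~40)
#' @param max_acq_sessions cap on acquisition sessions before flagging the
#'   criterion as unreached
#' @param n_reversal_sessions reversal sessions appended once the criterion
#'   is met
#' @param acquisition_learning_rate exponential learning-rate per trial of
#'   P(correct) during acquisition
#' @param asymptote asymptotic P(correct)
#' @param criterion session percent-correct triggering reversal (0.80)
#' @param pre_reversal_trials trials run under the old contingency at the
#'   start of the reversal session before the uncued switch
#' @param win_stay_p probability of repeating the arm after a reward
#' @param loseshift_intercept,loseshift_coupling logistic intercept and slope
#'   linking the simulated ACh amplitude (z units) to P(switch | no reward)
#' @param cin_inhibition_factor multiplier on `loseshift_coupling`
#'   (< 1 emulates chemogenetic inhibition of cholinergic interneurons)
#' @param ach_mean,ach_sd distribution of the simulated no-reward ACh
#'   response amplitude (z units)
#' @param latency_late_s,latency_early_s,latency_tau trial start-to-outcome
#'   latency: late asymptote, early value, and per-trial decay constant
#' @param lick_base,lick_anticip Poisson lick rates per 40-cm bin: baseline,
#'   and the extra anticipatory rate in the pre-outcome bin scaled by
#'   learned expectancy
#' @param iti_s inter-trial interval (s)
#' @param seed integer seed
#' @return a `behavior_params` object
#' @export
behavior_params <- function(trials_per_session = 40,
                            max_acq_sessions = 6,
                            n_reversal_sessions = 1,
                            acquisition_learning_rate = 0.02,
                            asymptote = 0.95,
                            criterion = 0.80,
                            pre_reversal_trials = 10,
                            win_stay_p = 0.95,
                            loseshift_intercept = -2,
                            loseshift_coupling = 1.0,
                            cin_inhibition_factor = 1,
                            ach_mean = 2.5, ach_sd = 0.8,
                            latency_late_s = 28, latency_early_s = 71,
                            latency_tau = 40,
                            lick_base = 0.5, lick_anticip = 6,
                            iti_s = 5, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$trials_per_session >= 1, p$criterion > 0, p$criterion <= 1,
            p$win_stay_p >= 0, p$win_stay_p <= 1,
            p$acquisition_learning_rate >= 0,
            p$asymptote >= 0.5, p$asymptote <= 1,
            p$cin_inhibition_factor >= 0)
  structure(p, class = "behavior_params")
}

#' Generate a synthetic reversal-learning trial table
#'
#' Simulates acquisition sessions with P(correct) rising toward the
#' asymptote, an uncued reversal once a session reaches the criterion, and
#' post-reversal choices driven by win-stay behavior after rewards and an
#' acetylcholine-coupled lose-shift rule after non-rewards:
#' P(switch | NR) = plogis(intercept + factor * coupling * ACh amplitude).
#' Per-trial lick counts per 40-cm maze bin and position samples are also
#' generated.
#'
#' @param params a [behavior_params()]
#' @return list of class `ach_behavior` with elements `trials` (one row per
#'   trial: session_day, trial_index, phase, chosen_arm, correct_arm,
#'   outcome, start/outcome times, latency, simulated ACh amplitude and
#'   switch probability on NR trials), `licks` (session_day, trial_index,
#'   bin 1-8, count, arm), `positions` (session_day, trial_index, t_s, y_cm)
#'   and attribute `criterion_reached`
#' @export
generate_behavior <- function(params = behavior_params()) {
  stopifnot(inherits(params, "behavior_params"))
  set.seed(params$seed)
  coupling <- params$loseshift_coupling * params$cin_inhibition_factor

  trials <- list(); licks <- list(); positions <- list()
  correct_arm <- "L"
  k_global <- 0                       # cumulative acquisition trial count
  phase <- "acquisition"
  criterion_reached <- FALSE
  reversed <- FALSE
  day <- 0
  prev_choice <- NULL
  sessions_left <- params$max_acq_sessions

  while (sessions_left > 0) {
    day <- day + 1
    is_rev_session <- criterion_reached
    n_tr <- params$trials_per_session
    t_clock <- 0
    sess_correct <- 0
    rev_at <- if (is_rev_session && !reversed)
      params$pre_reversal_trials else Inf

    for (i in seq_len(n_tr)) {
      if (i == rev_at + 1) {
        correct_arm <- if (correct_arm == "L") "R" else "L"
        phase <- "reversal"
        reversed <- TRUE
      }
      k_global <- k_global + 1
      p_corr <- 0.5 + (params$asymptote - 0.5) *
        (1 - exp(-params$acquisition_learning_rate * k_global))

      ach <- NA_real_; p_switch <- NA_real_
      if (phase == "acquisition" || is.null(prev_choice)) {
        chosen <- if (stats::runif(1) < p_corr) correct_arm
                  else setdiff(c("L", "R"), correct_arm)
      } else {
        # post-reversal: outcome-driven stay/shift on the previous choice
        prev_rewarded <- trials[[length(trials)]]$outcome == "R"
        if (prev_rewarded) {
          stay <- stats::runif(1) < params$win_stay_p
        } else {
          ach <- stats::rnorm(1, params$ach_mean, params$ach_sd)
          p_switch <- stats::plogis(params$loseshift_intercept +
                                      coupling * ach)
          stay <- stats::runif(1) >= p_switch
        }
        chosen <- if (stay) prev_choice
                  else setdiff(c("L", "R"), prev_choice)
      }
      outcome <- if (chosen == correct_arm) "R" else "NR"
      if (outcome == "R") sess_correct <- sess_correct + 1

      lat <- params$latency_late_s +
        (params$latency_early_s - params$latency_late_s) *
        exp(-k_global / params$latency_tau)
      lat <- max(5, lat * exp(stats::rnorm(1, 0, 0.1)))
      start_t <- t_clock
      out_t <- start_t + lat
      t_clock <- out_t + params$iti_s

      trials[[length(trials) + 1L]] <- data.frame(
        session_day = day, trial_index = i, phase = phase,
        chosen_arm = chosen, correct_arm = correct_arm, outcome = outcome,
        start_time_s = start_t, outcome_time_s = out_t, latency_s = lat,
        ach_amp = ach, p_switch = p_switch)

      # anticipatory licking: extra licks in the pre-outcome bin (280-320 cm)
      # when approaching the arm currently believed rewarded
      expects_reward <- chosen == correct_arm
      rate <- rep(params$lick_base, 8)
      if (expects_reward)
        rate[8] <- rate[8] + params$lick_anticip * (2 * p_corr - 1)
      licks[[length(licks) + 1L]] <- data.frame(
        session_day = day, trial_index = i, bin = 1:8,
        count = stats::rpois(8, rate), arm = chosen)

      # constant-speed traversal 0 -> 320 cm sampled at 2 Hz
      ts <- seq(0, lat, by = 0.5)
      positions[[length(positions) + 1L]] <- data.frame(
        session_day = day, trial_index = i, t_s = start_t + ts,
        y_cm = 320 * ts / lat)

      prev_choice <- chosen
    }

    if (is_rev_session) {
      sessions_left <- sessions_left - 1
    } else if (sess_correct / n_tr >= params$criterion) {
      criterion_reached <- TRUE
      sessions_left <- params$n_reversal_sessions
    } else {
      sessions_left <- sessions_left - 1
      if (sessions_left == 0)
        warning("acquisition criterion not reached within ",
                params$max_acq_sessions, " sessions")
    }
  }

  out <- list(trials = do.call(rbind, trials),
              licks = do.call(rbind, licks),
              positions = do.call(rbind, positions),
              params = params)
  attr(out, "criterion_reached") <- criterion_reached
  class(out) <- "ach_behavior"
  out
}

#' @export
print.ach_behavior <- function(x, ...) {
  cat(sprintf("ach_behavior: %d trials over %d sessions (%s)\n",
              nrow(x$trials), max(x$trials$session_day),
              if (isTRUE(attr(x, "criterion_reached")))
                "criterion reached" else "criterion NOT reached"))
  invisible(x)
}
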