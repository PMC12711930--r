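#' Choice selectivity index
#'
#' `(correct - incorrect) / (correct + incorrect)`, the maze-arm selectivity
#' score: -1 (always incorrect) to +1 (always correct).
#'
#' @param correct,incorrect trial counts
#' @param session optional label used in error messages
#' @return selectivity index in \[-1, 1\]
#' @export
choice_selectivity <- function(correct, incorrect, session = NULL) {
  stopifnot(correct >= 0, incorrect >= 0)
  tot <- correct + incorrect
  if (tot == 0)
    stop("no trials to compute selectivity",
         if (!is.null(session)) paste0(" for session ", session))
  (correct - incorrect) / tot
}

#' Anticipatory lick-frequency index
#'
#' `(licks_reward_arm - licks_noreward_arm) / (sum)`, computed per 40-cm
#' maze bin. Bins with zero licks on both arms are undefined and return
#' `NA` so they can be excluded from downstream regressions, never treated
#' as 0.
#'
#' @param licks_reward_arm,licks_noreward_arm lick counts (vectorised over
#'   bins)
#' @return index in \[-1, 1\], `NA` where both counts are zero
#' @export
lick_frequency_index <- function(licks_reward_arm, licks_noreward_arm) {
  stopifnot(all(licks_reward_arm >= 0), all(licks_noreward_arm >= 0))
  tot <- licks_reward_arm + licks_noreward_arm
  ifelse(tot == 0, NA_real_, (licks_reward_arm - licks_noreward_arm) / tot)
}

#' Classify a session as early or late in learning
#'
#' A session is `early` if its selectivity score is below 0.3 and it falls
#' on training day 2 or earlier; `late` if selectivity is at least 0.6 on
#' day 4 or later; otherwise `neither`.
#'
#' @param selectivity selectivity index in \[-1, 1\]
#' @param session_day training day (1-based)
#' @return `"early"`, `"late"` or `"neither"`
#' @export
classify_session_phase <- function(selectivity, session_day) {
  stopifnot(selectivity >= -1, selectivity <= 1, session_day >= 1)
  if (selectivity < 0.3 && session_day <= 2) "early"
  else if (selectivity >= 0.6 && session_day >= 4) "late"
  else "neither"
}

#' Velocity profile over maze position bins
#'
#' Finite-difference velocity dY/dt from position samples, averaged within
#' eight 40-cm bins covering 0-320 cm. Each finite-difference segment is
#' assigned to the bin containing its midpoint position.
#'
#' @param position_samples data.frame with columns `t_s` (strictly
#'   increasing) and `y_cm`
#' @param bin_width_cm bin width, default 40
#' @param range_cm maze extent covered, default c(0, 320)
#' @return numeric vector of mean velocities (cm/s) per bin, `NA` for bins
#'   with no samples
#' @export
velocity_profile <- function(position_samples, bin_width_cm = 40,
                             range_cm = c(0, 320)) {
  stopifnot(is.data.frame(position_samples),
            all(c("t_s", "y_cm") %in% names(position_samples)),
            nrow(position_samples) >= 2)
  t <- position_samples$t_s
  y <- position_samples$y_cm
  if (any(diff(t) <= 0))
    stop("position timestamps must be strictly increasing")
  v <- diff(y) / diff(t)
  mid <- (y[-1] + y[-length(y)]) / 2
  breaks <- seq(range_cm[1], range_cm[2], by = bin_width_cm)
  bin <- cut(mid, breaks = breaks, right = FALSE, labels = FALSE)
  out <- rep(NA_real_, length(breaks) - 1)
  ok <- !is.na(bin)
  if (any(ok)) {
    m <- tapply(v[ok], bin[ok], mean)
    out[as.integer(names(m))] <- m
  }
  out
}

#' Win-stay and lose-shift probabilities
#'
#' Trial-by-trial choice strategy conditioned on the previous trial's
#' outcome: P(win-stay) is the fraction of rewarded trials (with a
#' successor) followed by the same arm; P(lose-shift) the fraction of
#' unrewarded trials followed by the other arm.
#'
#' @param chosen_arm character vector of arm choices ("L"/"R"), in trial
#'   order
#' @param outcome character vector, "R" (rewarded) or "NR"
#' @return list with `win_stay`, `lose_shift` (each `NA` with a flag when no
#'   qualifying trials exist), and the transition counts `n_win`, `n_lose`
#' @export
winstay_loseshift <- function(chosen_arm, outcome) {
  n <- length(chosen_arm)
  stopifnot(length(outcome) == n, n >= 2)
  prev_out <- outcome[-n]
  stay <- chosen_arm[-1] == chosen_arm[-n]
  win <- prev_out == "R"
  lose <- prev_out == "NR"
  ws <- if (any(win)) mean(stay[win]) else NA_real_
  ls <- if (any(lose)) mean(!stay[lose]) else NA_real_
  if (!any(win)) warning("no rewarded trials with a successor: win-stay undefined")
  if (!any(lose)) warning("no unrewarded trials with a successor: lose-shift undefined")
  list(win_stay = ws, lose_shift = ls,
       n_win = sum(win), n_lose = sum(lose))
}

#' Perseverative and regressive error counts after reversal
#'
#' The post-reversal trial sequence is scanned in consecutive,
#' non-overlapping blocks of four trials. While blocks contain three or
#' more incorrect trials (the perseverative sequence), every error in them
#' counts as perseverative. The sequence ends at the first block with two
#' or more correct trials; from that block onward every error counts as
#' regressive (errors after learning has been demonstrated). Trailing
#' trials that do not fill a block are ignored.
#'
#' @param correct logical (or 0/1) vector over post-reversal trials, TRUE =
#'   correct choice, starting at the first post-reversal trial
#' @return list with `perseverative`, `regressive` and `n_blocks`
#' @export
error_taxonomy <- function(correct) {
  correct <- as.logical(correct)
  n_blocks <- length(correct) %/% 4
  if (n_blocks == 0) {
    warning("fewer than 4 post-reversal trials: error counts are 0")
    return(list(perseverative = 0L, regressive = 0L, n_blocks = 0L))
  }
  persev <- 0L; regress <- 0L
  in_sequence <- TRUE
  for (b in seq_len(n_blocks)) {
    blk <- correct[(4 * b - 3):(4 * b)]
    errs <- sum(!blk)
    if (in_sequence && errs >= 3) {
      persev <- persev + errs
    } else {
      in_sequence <- FALSE
      regress <- regress + errs
    }
  }
  list(perseverative = persev, regressive = regress, n_blocks = n_blocks)
}

#' Trials to reach a moving-average performance criterion
#'
#' Index of the first trial at which the trailing moving-window fraction
#' correct reaches the criterion (0.80 by default, five-trial window as in
#' standard moving-average performance traces).
#'
#' @param correct logical (or 0/1) vector in trial order
#' @param criterion fraction correct to reach
#' @param window moving-window width in trials
#' @return integer trial index, or `NA_integer_` if never reached
#' @export
trials_to_criterion <- function(correct, criterion = 0.80, window = 5) {
  stopifnot(window >= 1, criterion > 0, criterion <= 1)
  correct <- as.logical(correct)
  n <- length(correct)
  if (n < window) return(NA_integer_)
  cs <- cumsum(correct)
  for (i in window:n) {
    frac <- (cs[i] - if (i > window) cs[i - window] else 0) / window
    if (frac >= criterion) return(i)
  }
  NA_integer_
}

#' Per-session behavioral summary
#'
#' Computes, per session, the selectivity index, percent correct,
#' early/late phase label, reward rate (rewards per second of session
#' time), and the anticipatory lick index in the pre-outcome bin
#' (280-320 cm).
#'
#' @param behavior an `ach_behavior` object from [generate_behavior()], or a
#'   list with compatible `trials` and `licks` data.frames
#' @return data.frame, one row per session
#' @export
summarize_sessions <- function(behavior) {
  tr <- behavior$trials
  lk <- behavior$licks
  days <- sort(unique(tr$session_day))
  out <- lapply(days, function(d) {
    td <- tr[tr$session_day == d, ]
    nc_ <- sum(td$outcome == "R")
    ni <- sum(td$outcome == "NR")
    sel <- choice_selectivity(nc_, ni, session = d)
    dur <- max(td$outcome_time_s) - min(td$start_time_s)
    ld <- lk[lk$session_day == d & lk$bin == 8, ]
    arm_r <- unique(td$correct_arm)[1]
    lr <- sum(ld$count[ld$arm == arm_r])
    ln <- sum(ld$count[ld$arm != arm_r])
    data.frame(session_day = d, n_trials = nrow(td),
               percent_correct = 100 * nc_ / nrow(td),
               selectivity = sel,
               phase_label = classify_session_phase(sel, d),
               reward_rate = nc_ / dur,
               lick_index_preoutcome = lick_frequency_index(lr, ln))
  })
  do.call(rbind, out)
}
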