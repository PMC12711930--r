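test_that("choice selectivity follows the index formula and is antisymmetric", {
  expect_equal(choice_selectivity(20, 20), 0)
  expect_equal(choice_selectivity(40, 0), 1)
  expect_equal(choice_selectivity(33, 7), 0.65)
  for (ci in list(c(5, 3), c(12, 30), c(1, 0))) {
    expect_equal(choice_selectivity(ci[1], ci[2]),
                 -choice_selectivity(ci[2], ci[1]))
  }
  expect_error(choice_selectivity(0, 0, session = 3), "session 3")
})

test_that("lick index: formula, antisymmetry and undefined bins as NA", {
  expect_equal(lick_frequency_index(10, 10), 0)
  expect_equal(lick_frequency_index(15, 0), 1)
  expect_equal(lick_frequency_index(12, 4), 0.5)
  expect_equal(lick_frequency_index(4, 12), -0.5)
  expect_true(is.na(lick_frequency_index(0, 0)))
  # vectorised over bins, NA never coerced to 0
  out <- lick_frequency_index(c(3, 0, 6), c(1, 0, 2))
  expect_equal(out, c(0.5, NA, 0.5))
})

test_that("sessions are split into early/late by the selectivity-and-day rule", {
  expect_equal(classify_session_phase(0.1, 1), "early")
  expect_equal(classify_session_phase(0.7, 5), "late")
  expect_equal(classify_session_phase(0.5, 3), "neither")
  expect_equal(classify_session_phase(0.29, 2), "early")
  expect_equal(classify_session_phase(0.6, 4), "late")
  expect_equal(classify_session_phase(0.1, 3), "neither")
  expect_equal(classify_session_phase(0.9, 2), "neither")
})

test_that("velocity profile averages dY/dt within 40-cm bins", {
  # constant 10 cm/s
  tr <- data.frame(t_s = seq(0, 32, by = 0.5),
                   y_cm = 10 * seq(0, 32, by = 0.5))
  expect_equal(velocity_profile(tr), rep(10, 8))
  # stationary animal
  tr0 <- data.frame(t_s = 0:10, y_cm = rep(5, 11))
  expect_equal(velocity_profile(tr0)[1], 0)
  # piecewise 5 cm/s then 20 cm/s with the change at 160 cm
  t1 <- seq(0, 32, by = 0.25)          # 0..160 cm at 5 cm/s
  t2 <- seq(32.125, 40, by = 0.125)    # 160..320 cm at 20 cm/s
  tr2 <- data.frame(t_s = c(t1, t2),
                    y_cm = c(5 * t1, 160 + 20 * (t2 - 32)))
  v <- velocity_profile(tr2)
  expect_equal(v[1:4], rep(5, 4), tolerance = 0.05)
  expect_equal(v[5:8], rep(20, 4), tolerance = 0.05)
  expect_error(velocity_profile(data.frame(t_s = c(0, 0, 1),
                                           y_cm = c(0, 1, 2))),
               "strictly increasing")
})

test_that("win-stay / lose-shift transition probabilities by enumeration", {
  # all rewarded, always repeating the arm
  suppressWarnings(
    ws1 <- winstay_loseshift(c("L", "L", "L"), c("R", "R", "R")))
  expect_equal(ws1$win_stay, 1.0)
  # every no-reward followed by the same arm: lose-shift 0
  suppressWarnings(
    ls0 <- winstay_loseshift(c("L", "L", "L"), c("NR", "NR", "NR")))
  expect_equal(ls0$lose_shift, 0.0)
  # mixed sequence: enumerate the transitions by hand
  arm <- c("L", "R", "R", "L", "R")
  out <- c("NR", "R", "R", "NR", "R")
  # NR at 1 -> switch; R at 2 -> stay; R at 3 -> switch; NR at 4 -> switch
  r <- suppressWarnings(winstay_loseshift(arm, out))
  expect_equal(r$lose_shift, 1.0)
  expect_equal(r$win_stay, 0.5)
  expect_equal(r$n_lose, 2L)
  expect_equal(r$n_win, 2L)
  # undefined sides warn and return NA
  expect_warning(w <- winstay_loseshift(c("L", "R"), c("R", "R")),
                 "lose-shift undefined")
  expect_true(is.na(w$lose_shift))
})

test_that("perseverative/regressive errors follow the four-trial block rules", {
  # hand-traced: blocks [0,0,0,1] [1,1,0,1] [1,0,1,1] (1 = correct)
  seqc <- c(0, 0, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1)
  et <- error_taxonomy(seqc)
  expect_equal(et$perseverative, 3L)
  expect_equal(et$regressive, 2L)
  # never exits the perseverative sequence
  et_all <- error_taxonomy(rep(0, 12))
  expect_equal(et_all$perseverative, 12L)
  expect_equal(et_all$regressive, 0L)
  # all correct
  et_ok <- error_taxonomy(rep(1, 12))
  expect_equal(et_ok$perseverative, 0L)
  expect_equal(et_ok$regressive, 0L)
  # too short warns, returns zeros
  expect_warning(et_s <- error_taxonomy(c(0, 1, 0)), "fewer than 4")
  expect_equal(et_s$perseverative + et_s$regressive, 0L)
  # property: counts never exceed total errors
  set.seed(8)
  for (i in 1:50) {
    x <- rbinom(sample(8:40, 1), 1, runif(1))
    et <- suppressWarnings(error_taxonomy(x))
    expect_lte(et$perseverative + et$regressive, sum(x == 0))
  }
})

test_that("trials-to-criterion matches a brute-force moving-window scan", {
  expect_equal(trials_to_criterion(rep(1, 10), window = 5), 5L)
  expect_true(is.na(trials_to_criterion(rep(0, 30))))
  brute <- function(x, crit, w) {
    for (i in w:length(x))
      if (mean(x[(i - w + 1):i]) >= crit) return(i)
    NA_integer_
  }
  set.seed(5)
  for (i in 1:40) {
    # synthetic learner with a known switch point
    sp <- sample(5:30, 1)
    x <- c(rbinom(sp, 1, 0.3), rbinom(25, 1, 0.95))
    w <- sample(3:8, 1)
    expect_identical(trials_to_criterion(x, 0.8, w), brute(x, 0.8, w))
  }
})

test_that("reward rate is invariant to trial reordering and lose-shift rises with coupling", {
  b <- generate_behavior(behavior_params(seed = 2))
  s1 <- b$trials[b$trials$session_day == 1, ]
  rate <- sum(s1$outcome == "R") /
    (max(s1$outcome_time_s) - min(s1$start_time_s))
  perm <- s1[sample(nrow(s1)), ]
  rate_p <- sum(perm$outcome == "R") /
    (max(perm$outcome_time_s) - min(perm$start_time_s))
  expect_equal(rate, rate_p)

  mean_ls <- function(coupling, seeds) {
    mean(vapply(seeds, function(s) {
      b <- generate_behavior(behavior_params(loseshift_coupling = coupling,
                                             seed = s))
      rev <- b$trials[b$trials$phase == "reversal", ]
      suppressWarnings(
        winstay_loseshift(rev$chosen_arm, rev$outcome)$lose_shift)
    }, numeric(1)), na.rm = TRUE)
  }
  seeds <- 1:20
  ls <- vapply(c(0.2, 1, 4), mean_ls, numeric(1), seeds = seeds)
  expect_true(all(diff(ls) >= 0))
})
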