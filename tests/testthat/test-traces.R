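test_that("registration recovers injected integer shifts exactly", {
  # single bright dot translated by (2, -1): exhaustive-search ground truth
  tmpl <- matrix(0, 40, 40); tmpl[20, 20] <- 1
  fr <- matrix(0, 40, 40); fr[22, 19] <- 1
  mv <- ach_movie(array(c(tmpl, fr), dim = c(40, 40, 2)), 30)
  reg <- register_frames(mv, template_frame = tmpl, search_radius = 5)
  expect_equal(reg$shifts[2, ], c(2, -1))
  # corrected frame equals the template away from the fill border
  expect_equal(reg$corrected$frames[5:35, 5:35, 2], tmpl[5:35, 5:35])

  # already-aligned movie: all shifts zero, output equals input
  lay <- balanced_layout(grid = c(5, 5))
  g <- generate_movie(lay, compact_trials(2), dims = c(60, 60), seed = 2)
  reg0 <- register_frames(g$movie, search_radius = 4)
  expect_true(all(reg0$shifts == 0))
  expect_equal(reg0$corrected$frames, g$movie$frames)

  # known +/-3 px schedule on a synthetic movie is recovered exactly
  T_ <- dim(g$movie$frames)[3]
  set.seed(13)
  sched <- cbind(sample(-3:3, T_, TRUE), sample(-3:3, T_, TRUE))
  gj <- generate_movie(lay, compact_trials(2), dims = c(60, 60),
                       jitter_schedule = sched, seed = 2)
  regj <- register_frames(gj$movie, template_frame = g$movie$frames[, , 1],
                          search_radius = 6)
  expect_identical(regj$shifts, sched)
})

test_that("quadrat extraction tiles the field and averages blocks", {
  # 150x150 with a 15x15 grid: 225 traces of 10x10-pixel means
  frames <- array(rnorm(150 * 150 * 3, mean = 100), dim = c(150, 150, 3))
  mv <- ach_movie(frames, 30)
  tr <- extract_quadrat_traces(mv, smooth_sigma = 0)
  expect_equal(nrow(tr$F), 225)
  expect_equal(tr$F[1, 2], mean(frames[1:10, 1:10, 2]))
  q <- which(tr$grid_row == 3 & tr$grid_col == 5)
  expect_equal(tr$F[q, 1], mean(frames[21:30, 41:50, 1]))

  # uniform movie: every trace constant and equal (with smoothing on)
  mvu <- ach_movie(array(7, dim = c(30, 30, 5)), 30)
  tru <- extract_quadrat_traces(mvu, grid_shape = c(3, 3), smooth_sigma = 2)
  expect_true(all(abs(tru$F - 7) < 1e-9))

  # one bright quadrat: only that trace elevated
  fr2 <- array(1, dim = c(30, 30, 2))
  fr2[11:20, 21:30, ] <- 9                    # grid (2, 3)
  trb <- extract_quadrat_traces(ach_movie(fr2, 30), grid_shape = c(3, 3),
                                smooth_sigma = 0)
  hot <- which(trb$grid_row == 2 & trb$grid_col == 3)
  expect_equal(trb$F[hot, 1], 9)
  expect_true(all(trb$F[-hot, ] == 1))

  # non-divisible frame: centred crop, reported
  trc <- extract_quadrat_traces(ach_movie(array(1, c(32, 32, 2)), 30),
                                grid_shape = c(3, 3), smooth_sigma = 0)
  expect_equal(attr(trc, "crop"), c(2L, 2L))
  expect_error(extract_quadrat_traces(ach_movie(array(1, c(32, 32, 2)), 30),
                                      grid_shape = c(3, 3), crop = FALSE),
               "not divisible")
})

test_that("dF/F follows (F - F0)/F0 with per-trial baseline", {
  expect_equal(compute_dff(rep(5, 10), 1:3)$dff, rep(0, 10))
  d <- compute_dff(c(rep(100, 5), rep(200, 5)), 1:5)
  expect_equal(d$dff[6], 1.0)
  expect_equal(compute_dff(c(rep(100, 3), 110), 1:3)$dff[4], 0.10)
  bad <- compute_dff(c(0, 0, 0, 5), 1:3)
  expect_false(bad$valid)
  expect_true(all(is.na(bad$dff)))
})

test_that("z-scoring centres and scales by the pre-outcome baseline", {
  fr <- 30
  # flat trace: all-zero z via the flagged sd = 0 path
  flat <- rep(0.3, 300)
  a <- align_and_zscore(flat, outcome_times_s = 5, frame_rate = fr)
  expect_true(a$flagged_sd0[1])
  expect_true(all(a$z[1, ] == 0))

  # baseline with known mean/SD, dip to 0 -> z dip = -(mu/sd)
  set.seed(3)
  b <- rnorm(30, 0.2, 0.1)
  dff <- c(rep(0.2, 120), b, rep(0, 30))     # outcome at sample 151
  a2 <- align_and_zscore(dff, outcome_times_s = 150 / fr, frame_rate = fr)
  expect_equal(a2$baseline_mu[1], mean(b))
  expect_equal(a2$baseline_sd[1], sd(b))
  expect_equal(a2$z[1, 31], (0 - mean(b)) / sd(b))
  # z baseline has mean 0, SD 1 by construction
  expect_equal(mean(a2$z[1, 1:30]), 0, tolerance = 1e-9)
  expect_equal(sd(a2$z[1, 1:30]), 1, tolerance = 1e-9)

  # invariance to affine rescaling of raw F (gain and offset via F0 > 0)
  F <- 100 + cumsum(rnorm(300, 0, 0.5))
  d1 <- compute_dff(F, 1:60)$dff
  z1 <- align_and_zscore(d1, 5, frame_rate = fr)$z
  F2 <- 3 * F
  d2 <- compute_dff(F2, 1:60)$dff
  z2 <- align_and_zscore(d2, 5, frame_rate = fr)$z
  expect_equal(z1, z2, tolerance = 1e-9)

  # outcome too close to the edge is dropped with a message
  expect_message(
    a3 <- align_and_zscore(dff, outcome_times_s = c(0.5, 150 / fr),
                           frame_rate = fr),
    "dropped")
  expect_equal(a3$dropped, 1L)
})

test_that("noiseless pause trial recovers the template extremum after z-scoring", {
  lay <- balanced_layout(grid = c(5, 5))
  g <- generate_movie(lay, compact_trials(2), dims = c(50, 50),
                      noise_sd = 0, seed = 2)
  tr <- extract_quadrat_traces(g$movie, grid_shape = c(5, 5),
                               smooth_sigma = 0)
  q <- which(g$truth$type == "pause")[1]
  d <- compute_dff(tr$F[q, ], 1:60)
  a <- align_and_zscore(d$dff, compact_trials(2)$outcome_time_s[1],
                        frame_rate = 30, sd_fallback = lay$dff_per_z)
  qr <- quantify_outcome_response(a$z[1, ], attr(a$z, "times"))
  expect_equal(qr$dip_amplitude, -1.64, tolerance = 0.02)
  expect_equal(qr$time_to_dip, 0.48, tolerance = 1 / 30)
})

test_that("ACh-insensitive control channel shows no outcome-locked response", {
  lay <- balanced_layout(grid = c(5, 5))
  trials <- compact_trials(2)
  resp <- numeric(20)
  for (s in 1:20) {
    g <- generate_movie(lay, trials, dims = c(50, 50), noise_sd = 5,
                        control_channel = TRUE, seed = s)
    tr <- extract_quadrat_traces(g$control, grid_shape = c(5, 5),
                                 smooth_sigma = 0)
    z_mean <- vapply(1:25, function(q) {
      d <- compute_dff(tr$F[q, ], 1:60)
      a <- align_and_zscore(d$dff, trials$outcome_time_s, frame_rate = 30)
      mean(a$z[, attr(a$z, "times") >= 0])
    }, numeric(1))
    resp[s] <- mean(z_mean)
  }
  expect_lt(abs(mean(resp)), 0.1)
})

test_that("slice puff analysis removes bleaching and recovers peak height", {
  fr <- 20
  times <- seq(0, 25 - 1 / fr, by = 1 / fr)
  # no bleach, no response: corrected trace ~ 0, peak ~ 0
  F_flat <- rep(100, length(times))
  r0 <- slice_puff_analysis(F_flat, times, puff_onset_s = 5)
  expect_lt(max(abs(r0$dff_corrected)), 1e-9)

  # pure exponential bleach: residual < 1% of the bleach span
  F_bl <- 100 * exp(-0.01 * times)
  rb <- slice_puff_analysis(F_bl, times, puff_onset_s = 5)
  span <- diff(range((F_bl - mean(F_bl[times < 5])) /
                       mean(F_bl[times < 5])))
  expect_lt(max(abs(rb$dff_corrected)), 0.01 * span)

  # injected transient of known dF/F height on a bleaching baseline
  h <- 0.30
  bump <- h * exp(-((times - 6.5)^2) / (2 * 0.4^2))
  e_bl <- 100 * exp(-0.01 * times)
  F0b <- mean(e_bl[times >= 0.5 & times < 5])
  F_tr <- e_bl + F0b * bump
  rt <- slice_puff_analysis(F_tr, times, puff_onset_s = 5)
  expect_equal(max(rt$dff_corrected[times >= 5]), h, tolerance = 0.02 * h)
  expect_equal(rt$peak_time_s, 6.5, tolerance = 0.1)

  # fit windows must lie inside the recording
  expect_error(slice_puff_analysis(F_flat[times < 15], times[times < 15],
                                   puff_onset_s = 5),
               "outside the recording")
})
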