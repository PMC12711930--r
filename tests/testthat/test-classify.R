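test_that("outcome-response quantifier reads dip/peak/latency off the trace", {
  t <- fine_times()
  z0 <- rep(0, length(t))
  q0 <- quantify_outcome_response(z0, t)
  expect_equal(q0$dip_amplitude, 0)
  expect_equal(q0$time_to_dip, 0)           # tie-break earliest
  expect_equal(q0$peak_amplitude, 0)
  expect_true(is.na(q0$onset))

  # printed reward dip parameters used as ground truth
  zr <- template_eval(template_pause(-1.64, 0.23, 0.48), t)
  qr <- quantify_outcome_response(zr, t)
  expect_equal(qr$dip_amplitude, -1.64)
  expect_equal(qr$time_to_dip, 0.48)

  # printed no-reward dip parameters
  zn <- template_eval(template_pause(-0.89, 0.25, 0.65), t)
  qn <- quantify_outcome_response(zn, t)
  expect_equal(qn$dip_amplitude, -0.89)
  expect_equal(qn$time_to_dip, 0.65)

  expect_error(quantify_outcome_response(zr[t < 0.5], t[t < 0.5]),
               "outcome window")
})

test_that("PCA keeps the fewest components reaching 90% variance", {
  set.seed(2)
  # rank-1 matrix: one component carries everything
  r1 <- outer(rnorm(30), rnorm(12))
  expect_equal(pca_reduce(r1)$m, 1L)

  # two orthogonal patterns at 60/40 variance: two components
  n <- 400
  u <- c(rep(1, 6), rep(0, 6)); v <- c(rep(0, 6), rep(1, 6))
  X <- outer(rnorm(n, sd = sqrt(0.6)), u) + outer(rnorm(n, sd = sqrt(0.4)), v)
  expect_equal(pca_reduce(X)$m, 2L)

  # isotropic noise in d = 10: components carry ~1/10 each, so 9 needed
  Z <- matrix(rnorm(2000 * 10), 2000, 10)
  expect_equal(pca_reduce(Z)$m, 9L)

  expect_error(pca_reduce(matrix(1, 5, 4)), "constant")
})

test_that("complete-linkage clustering separates well-separated clouds", {
  set.seed(4)
  a <- matrix(rnorm(40, 0, 0.2), 20, 2)
  b <- matrix(rnorm(40, 10, 0.2), 20, 2)
  lab <- hcluster(rbind(a, b), k = 2)
  expect_equal(length(unique(lab[1:20])), 1L)
  expect_equal(length(unique(lab[21:40])), 1L)
  expect_true(lab[1] != lab[21])
  expect_equal(hcluster(rbind(a, b), k = 1), rep(1L, 40))
  expect_error(hcluster(a, k = 21))
})

test_that("elbow sits at the maximum second difference of WCSS", {
  expect_equal(elbow_k(c(100, 20, 18, 17, 16), ks = 1:5), 2L)
  # linear decay: no curvature anywhere, smallest interior candidate wins
  expect_equal(elbow_k(seq(100, 20, by = -20), ks = 1:5), 2L)
  expect_error(elbow_k(c(10, 5)), "at least 3")
  expect_error(elbow_k(c(10, 12, 5)), "non-increasing")
  # four equidistant-template synthetic data: elbow finds k = 4
  tml <- default_templates("R")
  tt <- seq(-1, 1 - 1 / 30, by = 1 / 30)
  M <- t(sapply(tml, function(tm) template_eval(tm, tt)))
  X <- M[rep(1:4, each = 40), ]
  expect_equal(elbow_k(wcss_curve(X, 1:8)), 4L)
})

test_that("silhouette matches a hand-computed case and the reference implementation", {
  # 1-D points 0, 1, 5 with labels {1, 1, 2}:
  # s(1) = (5 - 1)/5, s(2) = (4 - 1)/4, singleton s(3) = 0
  X <- matrix(c(0, 1, 5), ncol = 1)
  s3 <- silhouette_scores(X, c(1, 1, 2))
  expect_equal(s3$s, c(4 / 5, 3 / 4, 0))

  # two tight, well-separated clusters: mean near 1
  set.seed(5)
  Y <- rbind(matrix(rnorm(60, 0, 0.05), 30, 2),
             matrix(rnorm(60, 8, 0.05), 30, 2))
  laby <- rep(1:2, each = 30)
  sy <- silhouette_scores(Y, laby)
  expect_gt(sy$mean, 0.97)

  # fully interleaved labels: mean near 0
  Z <- matrix(rnorm(200), 100, 2)
  sz <- silhouette_scores(Z, rep(1:2, 50))
  expect_lt(abs(sz$mean), 0.1)

  # agreement with cluster::silhouette on a generic configuration
  ref <- cluster::silhouette(laby, dist(Y))
  expect_equal(sy$s, as.numeric(ref[, "sil_width"]), tolerance = 1e-12)
  expect_error(silhouette_scores(X, c(1, 1, 1)), "two clusters")
})

test_that("rule classification applies the SD thresholds with precedence", {
  t <- fine_times(0.01, c(0, 1))
  mk <- function(...) {
    lobes <- list(...)
    z <- rep(0, length(t))
    for (l in lobes) z <- z + l[1] * exp(-((t - l[2])^2) / (2 * 0.05^2))
    z
  }
  expect_equal(rule_classify(mk(c(-3, 0.5)), t), "decrease")
  expect_equal(rule_classify(mk(c(2.5, 0.2), c(-2.5, 0.7)), t),
               "increase-decrease")
  expect_equal(rule_classify(mk(c(-2.5, 0.3), c(2.5, 0.8)), t),
               "decrease-increase")
  expect_equal(rule_classify(mk(c(2.5, 0.6)), t), "increase")
  expect_equal(rule_classify(rep(0, length(t)), t), "unclassified")
  # dip below -2 with a small positive excursion: not decrease (exceeds
  # +1), not increase (dip disqualifies an early peak absent), unclassified
  expect_equal(rule_classify(mk(c(-3, 0.5), c(1.5, 0.15)), t),
               "unclassified")
  expect_error(rule_classify(c(NA, rep(0, length(t) - 1)), t), "undefined")
})

test_that("responsiveness runs a paired t-test with sign and epsilon guard", {
  ev <- rnorm(20)
  expect_equal(responsiveness(ev, ev)$label, "non-selective")
  r <- responsiveness(ev + 5, ev)
  expect_equal(r$label, "positive")        # constant shift, zero variance
  expect_equal(r$p_value, 0)
  expect_warning(r1 <- responsiveness(1, 2), "fewer than 2")
  expect_equal(r1$label, "non-selective")

  # power: true shift d = 1.5 with n = 20 trials detects >95% of the time
  set.seed(6)
  hits <- 0
  for (i in 1:1000) {
    base <- rnorm(20)
    evk <- base + rnorm(20, mean = 1.5)
    if (responsiveness(evk, base)$label == "positive") hits <- hits + 1
  }
  expect_gt(hits / 1000, 0.95)
})

test_that("ramp classification by 5-s regression slope", {
  fr <- 30
  t <- seq(-5, 0 - 1 / fr, by = 1 / fr)
  set.seed(7)
  up <- 0.2 * t + rnorm(length(t), 0, 0.01)
  expect_equal(ramp_classify(up, t)$label, "positive")
  expect_equal(ramp_classify(-0.2 * t + rnorm(length(t), 0, 0.01), t)$label,
               "negative")
  expect_error(ramp_classify(up[t > -3], t[t > -3]), "shorter")
})

test_that("switch/stay grouping combines the two responsiveness axes", {
  set.seed(8)
  base <- rnorm(40, 0, 0.3)
  sw <- rep(c(TRUE, FALSE), each = 20)
  # elevated only before switches
  ev1 <- base + ifelse(sw, 3, 0) + rnorm(40, 0, 0.2)
  g1 <- switch_stay_classify(ev1, base, sw)
  expect_equal(g1$group, "switch+/stayns")
  # identical elevation before both
  ev2 <- base + 3 + rnorm(40, 0, 0.2)
  expect_equal(switch_stay_classify(ev2, base, sw)$group, "switch+/stay+")
  # suppressed before stays only
  ev3 <- base + ifelse(sw, 0, -3) + rnorm(40, 0, 0.2)
  expect_equal(switch_stay_classify(ev3, base, sw)$group, "switchns/stay-")
  # an axis with < 2 trials is ns, flagged
  expect_warning(
    g4 <- switch_stay_classify(ev1, base, c(TRUE, rep(FALSE, 39))),
    "fewer than 2")
  expect_match(g4$group, "^switchns/")
})

test_that("switch/stay ground-truth groups are recovered on synthetic trials", {
  set.seed(9)
  n_quadrat <- 60
  groups <- sample(c("switch+/stayns", "switchns/stay-", "switch+/stay+"),
                   n_quadrat, replace = TRUE)
  recovered <- character(n_quadrat)
  sw <- rep(c(TRUE, FALSE), each = 20)
  for (q in seq_len(n_quadrat)) {
    base <- rnorm(40, 0, 0.3)
    mu_sw <- if (grepl("switch\\+", groups[q])) 2 else 0
    mu_st <- if (grepl("stay\\+", groups[q])) 2
             else if (grepl("stay-", groups[q])) -2 else 0
    ev <- base + ifelse(sw, mu_sw, mu_st) + rnorm(40, 0, 0.3)
    recovered[q] <- switch_stay_classify(ev, base, sw)$group
  }
  expect_gte(mean(recovered == groups), 0.95)
})

test_that("full-field mean z equals the quadrat-weighted mean of traces", {
  lay <- balanced_layout(grid = c(5, 5))
  trials <- compact_trials(3)
  g <- generate_movie(lay, trials, dims = c(50, 50), noise_sd = 2, seed = 4)
  tr <- extract_quadrat_traces(g$movie, grid_shape = c(5, 5),
                               smooth_sigma = 0)
  ar <- aligned_quadrat_responses(tr, trials$outcome_time_s)
  full <- colMeans(ar$mean_z)
  manual <- colMeans(apply(ar$z, c(1, 3), mean))
  expect_equal(full, manual, tolerance = 1e-12)
})
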