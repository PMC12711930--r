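#' Quantify an outcome-aligned response
#'
#' Dip and peak of a trial-averaged, baseline z-scored trace within the
#' outcome window \[0, 1) s: dip amplitude (minimum), time-to-dip, peak
#' amplitude (maximum), time-to-peak, and response onset (first |z| > 1
#' crossing, `NA` if none). Ties resolve to the earliest sample.
#'
#' @param z z-scored trace (vector)
#' @param times sample times in seconds relative to the outcome; taken from
#'   the `"times"` attribute of `z` if missing
#' @param window analysis window, default c(0, 1), half-open
#' @return list with `dip_amplitude`, `time_to_dip`, `peak_amplitude`,
#'   `time_to_peak`, `onset`
#' @export
quantify_outcome_response <- function(z, times = attr(z, "times"),
                                      window = c(0, 1)) {
  stopifnot(!is.null(times), length(z) == length(times))
  sel <- times >= window[1] & times < window[2]
  dt <- stats::median(diff(times))
  if (!any(sel) || min(times) > window[1] + 1e-9 ||
      max(times) < window[2] - dt - 1e-9)
    stop("trace does not cover the outcome window [",
         window[1], ", ", window[2], ") s")
  zs <- z[sel]; ts <- times[sel]
  i_min <- which.min(zs); i_max <- which.max(zs)
  cross <- which(abs(zs) > 1)
  list(dip_amplitude = zs[i_min], time_to_dip = ts[i_min],
       peak_amplitude = zs[i_max], time_to_peak = ts[i_max],
       onset = if (length(cross)) ts[cross[1]] else NA_real_)
}

#' PCA reduction retaining a target fraction of variance
#'
#' Principal components of the quadrat-by-time response matrix, keeping the
#' smallest number of components whose cumulative explained variance
#' reaches the target (90% by default).
#'
#' @param x numeric matrix, one row per quadrat
#' @param variance cumulative explained-variance target in (0, 1\]
#' @return list with `scores` (n x m), `m`, `explained` (per-component
#'   fraction) and `cumulative`
#' @export
pca_reduce <- function(x, variance = 0.90) {
  stopifnot(is.matrix(x), nrow(x) >= 2, all(is.finite(x)),
            variance > 0, variance <= 1)
  if (all(apply(x, 2, stats::sd) == 0))
    stop("constant matrix: no variance to decompose")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(expl)
  m <- which(cum >= variance - 1e-12)[1]
  list(scores = pc$x[, seq_len(m), drop = FALSE], m = m,
       explained = expl, cumulative = cum)
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering of component scores with the Euclidean metric
#' and complete linkage, cut into `k` groups.
#'
#' @param scores numeric matrix, one row per quadrat
#' @param k number of clusters, 1 <= k <= n
#' @return integer labels (1..k)
#' @export
hcluster <- function(scores, k) {
  n <- nrow(scores)
  stopifnot(k >= 1, k <= n)
  hc <- stats::hclust(stats::dist(scores, method = "euclidean"),
                      method = "complete")
  stats::cutree(hc, k = k)
}

#' Within-cluster sum of squares over candidate cluster counts
#'
#' @param scores numeric matrix, one row per observation
#' @param ks candidate cluster counts
#' @return numeric vector of WCSS, named by k
#' @export
wcss_curve <- function(scores, ks = 1:8) {
  hc <- stats::hclust(stats::dist(scores, method = "euclidean"),
                      method = "complete")
  vapply(ks, function(k) {
    lab <- stats::cutree(hc, k = k)
    sum(vapply(split(seq_len(nrow(scores)), lab), function(idx) {
      s <- scores[idx, , drop = FALSE]
      sum(sweep(s, 2, colMeans(s))^2)
    }, numeric(1)))
  }, numeric(1)) |> stats::setNames(ks)
}

#' Elbow choice of the number of clusters
#'
#' Selects the k at the maximum discrete second difference of the
#' (non-increasing) WCSS curve, i.e. the sharpest bend; ties resolve to the
#' smallest k. Requires at least three candidate counts.
#'
#' @param wcss numeric vector of within-cluster sums of squares, named by
#'   (or aligned with) consecutive candidate k values
#' @param ks candidate cluster counts, default from names
#' @return selected k
#' @export
elbow_k <- function(wcss, ks = as.integer(names(wcss))) {
  if (length(wcss) < 3)
    stop("elbow selection needs at least 3 candidate cluster counts")
  if (any(is.na(ks))) ks <- seq_along(wcss)
  if (any(diff(wcss) > 1e-8 * max(abs(wcss), 1)))
    stop("WCSS curve must be non-increasing in k")
  d2 <- wcss[-c(length(wcss) - 1, length(wcss))] -
    2 * wcss[-c(1, length(wcss))] + wcss[-(1:2)]
  ks[-c(1, length(ks))][which.max(d2)]
}

#' Silhouette coefficients
#'
#' Standard silhouette s(i) = (b - a) / max(a, b) with a the mean
#' within-cluster distance and b the smallest mean distance to another
#' cluster; members of singleton clusters score 0.
#'
#' @param scores numeric matrix, one row per observation
#' @param labels integer cluster labels (at least two non-empty clusters)
#' @return list with `s` (per observation), `cluster_mean` (named by
#'   cluster), `mean`, and `range`
#' @export
silhouette_scores <- function(scores, labels) {
  labs <- unique(labels)
  if (length(labs) < 2) stop("silhouette requires at least two clusters")
  D <- as.matrix(stats::dist(scores, method = "euclidean"))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(labs, labels[i]), function(l)
      mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  cm <- tapply(s, labels, mean)
  list(s = s, cluster_mean = cm, mean = mean(s), range = range(s))
}

#' Rule-based response-type classification
#'
#' Post-hoc taxonomy of a trial-averaged z-scored trace over the outcome
#' window, using fixed SD thresholds on the unit-SD baseline scale:
#' \describe{
#'   \item{increase-decrease}{exceeds +2 for at least one frame in
#'     \[0, 0.4) s, followed by a pause (minimum below -2 after the early
#'     peak, within \[0, 1) s)}
#'   \item{decrease-increase}{minimum below -2, plus a rebound above +2 in
#'     \[0.5, 1) s occurring after the dip}
#'   \item{decrease}{never exceeds +1 during \[0, 1) s and minimum below
#'     -2}
#'   \item{increase}{exceeds +2 during the outcome window without a
#'     qualifying decrease}
#' }
#' Precedence follows that order; anything else is `unclassified`.
#'
#' @param z trial-averaged z trace
#' @param times times in seconds relative to outcome (default from
#'   attribute)
#' @return one of `"decrease"`, `"increase-decrease"`,
#'   `"decrease-increase"`, `"increase"`, `"unclassified"`
#' @export
rule_classify <- function(z, times = attr(z, "times")) {
  stopifnot(!is.null(times), length(z) == length(times))
  if (any(!is.finite(z[times >= 0 & times < 1])))
    stop("undefined samples in the outcome window")
  win <- times >= 0 & times < 1
  zw <- z[win]; tw <- times[win]
  zmin <- min(zw); zmax <- max(zw)
  t_min <- tw[which.min(zw)]

  early <- tw < 0.4
  if (any(zw[early] > 2)) {
    t_peak_early <- tw[early][which.max(zw[early])]
    after <- tw > t_peak_early
    if (any(after) && min(zw[after]) < -2) return("increase-decrease")
  }
  late <- tw >= 0.5
  if (zmin < -2 && any(late) && any(zw[late] > 2)) {
    t_reb <- tw[late][which.max(zw[late])]
    if (t_min < t_reb) return("decrease-increase")
  }
  if (zmax <= 1 && zmin < -2) return("decrease")
  if (zmax > 2) return("increase")
  "unclassified"
}

#' Outcome responsiveness of a quadrat
#'
#' Two-tailed paired t-test of per-trial evoked activity (mean z over the
#' 0.3-1.3 s post-outcome window) against per-trial baseline activity
#' (mean over the 1-s pre-outcome window). P < alpha classifies the
#' quadrat as `positive` or `negative` by the sign of the mean difference;
#' otherwise `non-selective`. Degenerate inputs (fewer than 2 trials, or
#' zero-variance identical differences) are handled explicitly: constant
#' non-zero differences force the sign, constant zero differences are
#' non-selective.
#'
#' @param evoked,baseline per-trial mean values (equal length)
#' @param alpha significance level, default 0.05
#' @return list with `label`, `p_value`, `mean_diff`, `n`
#' @export
responsiveness <- function(evoked, baseline, alpha = 0.05) {
  stopifnot(length(evoked) == length(baseline))
  n <- length(evoked)
  if (n < 2) {
    warning("fewer than 2 paired trials: non-selective")
    return(list(label = "non-selective", p_value = NA_real_,
                mean_diff = NA_real_, n = n))
  }
  d <- evoked - baseline
  md <- mean(d)
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    # epsilon-guard: identical differences carry no sampling variance
    lab <- if (abs(md) < .Machine$double.eps^0.5) "non-selective"
           else if (md > 0) "positive" else "negative"
    return(list(label = lab, p_value = if (lab == "non-selective") 1 else 0,
                mean_diff = md, n = n))
  }
  p <- stats::t.test(evoked, baseline, paired = TRUE)$p.value
  lab <- if (p >= alpha) "non-selective"
         else if (md > 0) "positive" else "negative"
  list(label = lab, p_value = p, mean_diff = md, n = n)
}

#' Pre-outcome ramp classification
#'
#' Least-squares regression of z on time over the last 5 s before the
#' outcome; a slope significantly different from zero (t-test on the
#' slope, P < alpha) classifies the trace as a `positive` or `negative`
#' ramp, otherwise `ns`. The closed-form simple-regression t-test is used
#' so that large calibration simulations stay cheap.
#'
#' @param z z-scored trace over the pre-outcome window
#' @param times sample times in seconds (negative = before outcome);
#'   default from attribute
#' @param window regression window, default c(-5, 0)
#' @param alpha significance level
#' @return list with `label` ("positive"/"negative"/"ns"), `slope`,
#'   `p_value`
#' @export
ramp_classify <- function(z, times = attr(z, "times"), window = c(-5, 0),
                          alpha = 0.05) {
  stopifnot(!is.null(times), length(z) == length(times))
  sel <- times >= window[1] & times < window[2]
  if (sum(sel) < 3 || min(times) > window[1] + 1e-9)
    stop("pre-outcome window shorter than ", diff(window), " s")
  x <- times[sel]; y <- z[sel]
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  slope <- sum(xc * yc) / sxx
  res <- yc - slope * xc
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  lab <- if (!is.finite(p) || p >= alpha) "ns"
         else if (slope > 0) "positive" else "negative"
  list(label = lab, slope = slope, p_value = p)
}

#' Switch/stay encoding group of a quadrat
#'
#' Unrewarded trials are split by the upcoming choice (switch to the other
#' arm vs stay). [responsiveness()] is run separately on the
#' switch-preceding and stay-preceding trials; the two axis labels
#' (positive / negative / non-selective, 'ns' when a condition has fewer
#' than 2 trials) combine into one of nine groups, e.g. `"switch+/stay-"`
#' or `"switch+/stay-ns"`.
#'
#' @param evoked,baseline per-NR-trial mean z values (see
#'   [responsiveness()])
#' @param next_switch logical per NR trial: TRUE if the upcoming choice
#'   switches arm
#' @param alpha significance level
#' @return list with `group` (e.g. `"switch+/stay-ns"`), `switch`, `stay`
#'   (the two [responsiveness()] results)
#' @export
switch_stay_classify <- function(evoked, baseline, next_switch,
                                 alpha = 0.05) {
  stopifnot(length(evoked) == length(baseline),
            length(next_switch) == length(evoked))
  run_axis <- function(sel) {
    if (sum(sel) < 2) {
      warning("fewer than 2 trials on one switch/stay axis: ns")
      list(label = "non-selective", p_value = NA_real_,
           mean_diff = NA_real_, n = sum(sel))
    } else responsiveness(evoked[sel], baseline[sel], alpha)
  }
  sw <- run_axis(next_switch)
  st <- run_axis(!next_switch)
  tag <- function(lab) switch(lab, positive = "+", negative = "-",
                              "non-selective" = "ns")
  list(group = paste0("switch", tag(sw$label), "/stay", tag(st$label)),
       switch = sw, stay = st)
}

#' Per-quadrat evoked and baseline means for responsiveness testing
#'
#' Convenience reduction of an aligned z (or delta-F/F) trial matrix to the
#' per-trial mean over an evoked window and a baseline window.
#'
#' @param z n_trial x n_time matrix with a `"times"` attribute
#' @param evoked_window default c(0.3, 1.3) s after the outcome
#' @param baseline_window default c(-1, 0) s
#' @return list with `evoked` and `baseline` per-trial means
#' @export
evoked_baseline_means <- function(z, evoked_window = c(0.3, 1.3),
                                  baseline_window = c(-1, 0)) {
  times <- attr(z, "times")
  stopifnot(!is.null(times))
  ev <- times >= evoked_window[1] & times < evoked_window[2]
  bl <- times >= baseline_window[1] & times < baseline_window[2]
  stopifnot(any(ev), any(bl))
  list(evoked = rowMeans(z[, ev, drop = FALSE]),
       baseline = rowMeans(z[, bl, drop = FALSE]))
}
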