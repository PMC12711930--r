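#' Outcome-aligned z-scored responses for every quadrat
#'
#' For each quadrat and each trial: baseline fluorescence F0 is the mean
#' over the 2-s pre-tone period (per trial), the window around the outcome
#' is converted to delta-F/F against that F0, and z-scored against the 1-s
#' pre-outcome delta-F/F baseline. When tone times are not supplied the
#' pre-tone baseline defaults to the 2 s ending at the start of the
#' outcome window.
#'
#' @param traces a `quadrat_traces` object from [extract_quadrat_traces()]
#' @param outcome_times_s outcome time per trial (s from recording start)
#' @param tone_times_s optional tone (trial start cue) time per trial
#' @param window,baseline outcome-aligned windows in s, half-open; see
#'   [align_and_zscore()]
#' @param pretone_s length of the pre-tone F0 window (s)
#' @param sd_fallback nominal baseline SD for zero-SD (noiseless) trials
#' @return list with `z` (n_quadrat x n_trial x n_time array, `"times"`
#'   attribute), `mean_z` (n_quadrat x n_time trial average), `f0`
#'   (n_quadrat x n_trial), `flagged_sd0`, `invalid_f0` (logical matrices),
#'   `times`
#' @export
aligned_quadrat_responses <- function(traces, outcome_times_s,
                                      tone_times_s = NULL,
                                      window = c(-1, 1),
                                      baseline = c(-1, 0),
                                      pretone_s = 2,
                                      sd_fallback = NULL) {
  stopifnot(inherits(traces, "quadrat_traces"))
  fr <- traces$frame_rate
  nq <- nrow(traces$F)
  n_time_total <- ncol(traces$F)
  rel <- seq(window[1], window[2] - 1 / fr, by = 1 / fr)
  offs <- round(rel * fr)
  base_sel <- rel >= baseline[1] & rel < baseline[2]
  if (is.null(tone_times_s))
    tone_times_s <- outcome_times_s + window[1]
  stopifnot(length(tone_times_s) == length(outcome_times_s))

  out_frames <- round(outcome_times_s * fr) + 1L
  keep <- vapply(seq_along(out_frames), function(i) {
    f <- out_frames[i]
    f0_start <- round((tone_times_s[i] - pretone_s) * fr) + 1L
    f + min(offs) >= 1 && f + max(offs) <= n_time_total && f0_start >= 1
  }, logical(1))
  if (any(!keep))
    message(sum(!keep), " trial(s) dropped: window outside recording")
  oc <- out_frames[keep]
  tn <- tone_times_s[keep]
  nt <- length(oc)
  if (nt == 0) stop("no usable trials")

  z <- array(NA_real_, dim = c(nq, nt, length(rel)))
  f0 <- matrix(NA_real_, nq, nt)
  flagged <- invalid <- matrix(FALSE, nq, nt)
  for (i in seq_len(nt)) {
    f0_idx <- (round((tn[i] - pretone_s) * fr) + 1L):round(tn[i] * fr)
    f0_idx <- f0_idx[f0_idx >= 1 & f0_idx <= n_time_total]
    seg_idx <- oc[i] + offs
    for (q in seq_len(nq)) {
      F0 <- mean(traces$F[q, f0_idx])
      f0[q, i] <- F0
      if (!is.finite(F0) || F0 <= 0) { invalid[q, i] <- TRUE; next }
      dff <- (traces$F[q, seg_idx] - F0) / F0
      b <- dff[base_sel]
      mu <- mean(b); sdb <- stats::sd(b)
      if (!is.finite(sdb) || sdb == 0) {
        flagged[q, i] <- TRUE
        sdb <- if (is.null(sd_fallback)) 1 else sd_fallback
      }
      z[q, i, ] <- (dff - mu) / sdb
    }
  }
  mean_z <- apply(z, c(1, 3), mean)
  attr(z, "times") <- rel
  attr(mean_z, "times") <- rel
  list(z = z, mean_z = mean_z, f0 = f0, flagged_sd0 = flagged,
       invalid_f0 = invalid, times = rel)
}

#' Cluster and classify quadrats from trial-averaged responses
#'
#' The spatiotemporal classification stage: PCA retaining 90% of variance,
#' complete-linkage hierarchical clustering with the cluster count chosen
#' by the elbow of the WCSS curve (or pinned via `k`), silhouette
#' diagnostics, and the rule-based response-type label per quadrat.
#'
#' @param mean_z n_quadrat x n_time matrix of trial-averaged z traces with
#'   a `"times"` attribute (times relative to outcome)
#' @param ks candidate cluster counts for the WCSS curve
#' @param k optional pinned cluster count (skips the elbow)
#' @param variance PCA explained-variance target
#' @return list with `labels` (cluster id per quadrat), `k`, `wcss`,
#'   `silhouette`, `rule_type` (character per quadrat), `pca`
#' @export
classify_quadrats <- function(mean_z, ks = 1:8, k = NULL,
                              variance = 0.90) {
  times <- attr(mean_z, "times")
  stopifnot(!is.null(times))
  pca <- pca_reduce(mean_z, variance = variance)
  wcss <- wcss_curve(pca$scores, ks = ks)
  k_use <- if (is.null(k)) elbow_k(wcss) else k
  labels <- hcluster(pca$scores, k_use)
  sil <- if (k_use >= 2) silhouette_scores(pca$scores, labels) else NULL
  rules <- apply(mean_z, 1, function(zrow) rule_classify(zrow, times))
  list(labels = labels, k = k_use, wcss = wcss, silhouette = sil,
       rule_type = rules, pca = pca)
}

#' Write a per-quadrat label table
#'
#' @param path output CSV path
#' @param truth optional ground-truth data.frame (from [generate_movie()])
#'   merged in by quadrat index
#' @param classification result of [classify_quadrats()]
#' @param coords optional result of [quadrat_coords()]
#' @return the written data.frame, invisibly
#' @export
write_label_table <- function(path, classification, truth = NULL,
                              coords = NULL) {
  df <- data.frame(quadrat = seq_along(classification$labels),
                   cluster = classification$labels,
                   rule_type = classification$rule_type)
  if (!is.null(coords)) df <- cbind(df, coords)
  if (!is.null(truth))
    df <- merge(df, truth, by = "quadrat", sort = TRUE,
                suffixes = c("", ".truth"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
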