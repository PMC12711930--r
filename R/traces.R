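#' Rigid motion registration by normalized cross-correlation
#'
#' Estimates one integer (dy, dx) translation per frame by maximizing the
#' normalized cross-correlation between a central crop of the template and
#' the corresponding window of the frame, over all shifts within
#' `search_radius` pixels, then translates each frame back (border filled
#' with the frame median). Cropping the template by the search radius keeps
#' the correlated area identical for every candidate shift, so the
#' criterion is a true correlation coefficient everywhere.
#'
#' @param movie an [ach_movie()]
#' @param template_frame H x W reference image; defaults to the movie's
#'   mean projection
#' @param search_radius maximum |shift| searched per axis (px)
#' @return list with `shifts` (T x 2 estimated (dy, dx)) and `corrected`
#'   (an `ach_movie` with the inverse translations applied)
#' @export
register_frames <- function(movie, template_frame = NULL,
                            search_radius = 8) {
  stopifnot(inherits(movie, "ach_movie"), search_radius >= 1)
  d <- dim(movie$frames)
  H <- d[1]; W <- d[2]; T_ <- d[3]
  if (is.null(template_frame))
    template_frame <- apply(movie$frames, c(1, 2), mean)
  stopifnot(nrow(template_frame) == H, ncol(template_frame) == W)
  r <- as.integer(search_radius)
  if (H <= 2 * r + 2 || W <= 2 * r + 2)
    stop("frame too small for search radius ", r)

  rows_c <- (r + 1):(H - r)
  cols_c <- (r + 1):(W - r)
  tc <- template_frame[rows_c, cols_c]
  tc <- tc - mean(tc)
  tnorm <- sqrt(sum(tc^2))
  if (tnorm == 0) {
    warning("constant template: all shifts set to (0, 0)")
    return(list(shifts = matrix(0L, T_, 2), corrected = movie))
  }
  # cross-correlation numerator via FFT (the template is zero-mean, so the
  # window mean drops out); window norms via integral images
  tpad <- matrix(0, H, W)
  tpad[rows_c, cols_c] <- tc
  Ft_conj <- Conj(stats::fft(tpad))
  h <- length(rows_c); w <- length(cols_c)
  npx <- h * w
  dys <- -r:r; dxs <- -r:r
  # circular index of shift dy in the FFT cross-correlation array
  iy <- ((dys %% H) + 1L)
  ix <- ((dxs %% W) + 1L)
  shifts <- matrix(0L, T_, 2)
  corrected <- movie$frames
  for (t in seq_len(T_)) {
    fr <- movie$frames[, , t]
    if (stats::sd(fr) == 0) {
      warning("constant frame ", t, ": shift set to (0, 0)")
      next
    }
    cc <- Re(stats::fft(Ft_conj * stats::fft(fr), inverse = TRUE)) / (H * W)
    num <- cc[iy, ix, drop = FALSE]
    # integral images: P[y+1, x+1] = sum fr[1:y, 1:x]
    P1 <- matrix(0, H + 1, W + 1)
    P1[-1, -1] <- apply(apply(fr, 2, cumsum), 1, cumsum) |> t()
    P2 <- matrix(0, H + 1, W + 1)
    P2[-1, -1] <- apply(apply(fr^2, 2, cumsum), 1, cumsum) |> t()
    box <- function(P, y1, y2, x1, x2)
      P[y2 + 1, x2 + 1] - P[y1, x2 + 1] - P[y2 + 1, x1] + P[y1, x1]
    best <- -Inf; bdy <- 0L; bdx <- 0L
    for (a in seq_along(dys)) for (b in seq_along(dxs)) {
      y1 <- rows_c[1] + dys[a]; y2 <- rows_c[h] + dys[a]
      x1 <- cols_c[1] + dxs[b]; x2 <- cols_c[w] + dxs[b]
      s1 <- box(P1, y1, y2, x1, x2)
      s2 <- box(P2, y1, y2, x1, x2)
      wvar <- s2 - s1^2 / npx
      if (wvar <= 0) next
      ncc <- num[a, b] / (tnorm * sqrt(wvar))
      if (ncc > best) { best <- ncc; bdy <- dys[a]; bdx <- dxs[b] }
    }
    shifts[t, ] <- c(bdy, bdx)
    if (bdy != 0 || bdx != 0)
      corrected[, , t] <- shift_frame(fr, -bdy, -bdx)
  }
  list(shifts = shifts, corrected = ach_movie(corrected, movie$frame_rate))
}

#' Separable spatiotemporal Gaussian smoothing
#'
#' Applies a Gaussian filter of the same sigma (in samples) along x, y and
#' t, with reflective boundaries, as a denoising step before quadrat
#' averaging.
#'
#' @param frames H x W x T array
#' @param sigma Gaussian SD in pixels/frames; 0 disables smoothing
#' @return smoothed array of the same dimensions
#' @export
gaussian_smooth_xyt <- function(frames, sigma = 2) {
  if (sigma <= 0) return(frames)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  d <- dim(frames)
  smooth_along <- function(a, margin) {
    # move target dim first, filter columns with edge reflection
    perm <- c(margin, setdiff(1:3, margin))
    m <- aperm(a, perm)
    dm <- dim(m)
    mm <- matrix(m, nrow = dm[1])
    n <- dm[1]
    hp <- min(half, n)
    idx <- c(rep(1L, half - hp), rev(seq_len(hp)), seq_len(n),
             n + 1 - seq_len(hp), rep(n, half - hp))
    padded <- mm[idx, , drop = FALSE]
    out <- stats::filter(padded, kern, sides = 2)  # filters each column
    out <- as.matrix(out)[(half + 1):(half + n), , drop = FALSE]
    dim(out) <- dm
    aperm(out, order(perm))
  }
  for (mrg in c(1, 2, 3)) frames <- smooth_along(frames, mrg)
  frames
}

#' Extract per-quadrat mean-intensity traces from a movie
#'
#' Tiles the field of view into a `grid_shape` grid of equal quadrats and
#' averages pixel intensities within each quadrat per frame, optionally
#' after spatiotemporal Gaussian denoising (sigma = 2 px in x, y and t by
#' default). If the frame is not divisible by the grid, a centred symmetric
#' crop to divisibility is applied and reported via the `"crop"` attribute
#' (or an error is raised when `crop = FALSE`).
#'
#' @param movie an [ach_movie()]
#' @param grid_shape c(rows, cols), default 15 x 15
#' @param smooth_sigma Gaussian sigma for denoising (0 = none)
#' @param crop allow centred cropping to divisibility
#' @return a `quadrat_traces` object: list with `F` (n_quadrat x T matrix of
#'   raw mean intensities, quadrats in column-major grid order), `grid_row`,
#'   `grid_col`, `grid_shape`, `frame_rate`
#' @export
extract_quadrat_traces <- function(movie, grid_shape = c(15, 15),
                                   smooth_sigma = 2, crop = TRUE) {
  stopifnot(inherits(movie, "ach_movie"), length(grid_shape) == 2L)
  frames <- movie$frames
  d <- dim(frames)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  crop_info <- c(0L, 0L)
  if (d[1] %% nr != 0 || d[2] %% nc != 0) {
    if (!crop)
      stop("frame ", d[1], "x", d[2], " not divisible by grid ",
           nr, "x", nc)
    keep_h <- (d[1] %/% nr) * nr
    keep_w <- (d[2] %/% nc) * nc
    off_h <- (d[1] - keep_h) %/% 2
    off_w <- (d[2] - keep_w) %/% 2
    frames <- frames[off_h + seq_len(keep_h), off_w + seq_len(keep_w), ,
                     drop = FALSE]
    crop_info <- c(d[1] - keep_h, d[2] - keep_w)
    d <- dim(frames)
  }
  if (smooth_sigma > 0)
    frames <- gaussian_smooth_xyt(frames, smooth_sigma)
  T_ <- d[3]
  Fm <- matrix(0, nr * nc, T_)
  for (t in seq_len(T_))
    Fm[, t] <- as.vector(block_mean(frames[, , t], nr, nc))
  out <- list(F = Fm,
              grid_row = rep(seq_len(nr), times = nc),
              grid_col = rep(seq_len(nc), each = nr),
              grid_shape = grid_shape,
              frame_rate = movie$frame_rate)
  attr(out, "crop") <- crop_info
  class(out) <- "quadrat_traces"
  out
}

#' @export
print.quadrat_traces <- function(x, ...) {
  cat(sprintf("quadrat_traces: %d quadrats (%d x %d grid), %d frames @ %g Hz\n",
              nrow(x$F), x$grid_shape[1], x$grid_shape[2], ncol(x$F),
              x$frame_rate))
  invisible(x)
}

#' Delta-F/F of a fluorescence trace
#'
#' `(F(t) - F0) / F0` with F0 the mean of F over the baseline window
#' (in vivo: the 2-s pre-tone period of each trial).
#'
#' @param F raw fluorescence series
#' @param baseline_idx integer indices of the baseline samples
#' @return list with `dff` and `F0`; `valid = FALSE` flags F0 <= 0 (the
#'   `dff` is then `NA`)
#' @export
compute_dff <- function(F, baseline_idx) {
  stopifnot(length(baseline_idx) >= 1,
            all(baseline_idx >= 1), all(baseline_idx <= length(F)))
  F0 <- mean(F[baseline_idx])
  if (!is.finite(F0) || F0 <= 0)
    return(list(dff = rep(NA_real_, length(F)), F0 = F0, valid = FALSE))
  list(dff = (F - F0) / F0, F0 = F0, valid = TRUE)
}

#' Outcome-aligned, baseline z-scored responses
#'
#' Cuts windows around each outcome from a delta-F/F series and z-scores
#' them against the immediately pre-outcome baseline:
#' z(t) = (dff(t) - mu) / SD with mu, SD from the baseline window
#' (default the 1 s before outcome, half-open). Trials whose window falls
#' outside the recording are dropped and reported; trials with zero
#' baseline SD are flagged and, unless `sd_fallback` is supplied, scored
#' with SD treated as 1 (centring only).
#'
#' @param dff delta-F/F series for one quadrat
#' @param outcome_times_s outcome times in seconds from recording start
#' @param frame_rate Hz
#' @param window c(start, end) seconds around outcome, half-open; default
#'   \[-1, +1)
#' @param baseline c(start, end) seconds, half-open; default \[-1, 0)
#' @param sd_fallback nominal baseline SD used for flagged zero-SD trials
#'   (e.g. a known noise floor on noiseless synthetic data)
#' @return list with `z` (n_trial x n_time matrix, `"times"` attribute),
#'   `baseline_mu`, `baseline_sd`, `flagged_sd0` (logical per kept trial),
#'   `dropped` (indices of out-of-range trials)
#' @export
align_and_zscore <- function(dff, outcome_times_s, frame_rate = 30,
                             window = c(-1, 1), baseline = c(-1, 0),
                             sd_fallback = NULL) {
  stopifnot(length(window) == 2L, window[1] < window[2],
            length(baseline) == 2L, baseline[1] < baseline[2],
            baseline[1] >= window[1], baseline[2] <= window[2])
  n <- length(dff)
  rel <- seq(window[1], window[2] - 1 / frame_rate, by = 1 / frame_rate)
  base_sel <- rel >= baseline[1] & rel < baseline[2]
  out_frames <- round(outcome_times_s * frame_rate) + 1L
  offs <- round(rel * frame_rate)
  keep <- vapply(out_frames, function(f)
    f + min(offs) >= 1 && f + max(offs) <= n, logical(1))
  dropped <- which(!keep)
  if (length(dropped) > 0)
    message(length(dropped), " trial(s) dropped: window outside recording")
  kept <- out_frames[keep]
  z <- matrix(NA_real_, length(kept), length(rel))
  mu <- sd_ <- numeric(length(kept))
  flagged <- logical(length(kept))
  for (i in seq_along(kept)) {
    seg <- dff[kept[i] + offs]
    b <- seg[base_sel]
    mu[i] <- mean(b)
    sd_[i] <- stats::sd(b)
    if (!is.finite(sd_[i]) || sd_[i] == 0) {
      flagged[i] <- TRUE
      sd_use <- if (is.null(sd_fallback)) 1 else sd_fallback
    } else sd_use <- sd_[i]
    z[i, ] <- (seg - mu[i]) / sd_use
  }
  attr(z, "times") <- rel
  list(z = z, baseline_mu = mu, baseline_sd = sd_,
       flagged_sd0 = flagged, dropped = dropped)
}

#' Bleach-corrected response to an acetylcholine puff in a brain slice
#'
#' Converts a slice fluorescence trace to delta-F/F against the pre-puff
#' baseline (default the 4.5 s before puff onset), removes photobleaching
#' by subtracting a B-spline fit to the trace restricted to the two
#' response-free windows (defaults 0.5-4.5 s and 14.5-19.5 s; the puff
#' response in between is masked out of the fit), z-scores the corrected
#' trace against the pre-puff baseline, and reports the post-puff peak.
#'
#' @param F raw fluorescence series
#' @param times_s sample times in seconds
#' @param puff_onset_s time of the puff
#' @param fit_windows list of two c(start, end) windows used for the
#'   bleach fit
#' @param baseline_s length of the pre-puff baseline for F0 (s)
#' @param spline_df degrees of freedom of the natural B-spline bleach model
#' @return list with `z` (bleach-corrected z trace), `dff_corrected`,
#'   `bleach_fit`, `peak` (max z after the puff) and `peak_time_s`
#' @export
slice_puff_analysis <- function(F, times_s, puff_onset_s,
                                fit_windows = list(c(0.5, 4.5),
                                                   c(14.5, 19.5)),
                                baseline_s = 4.5, spline_df = 5) {
  stopifnot(length(F) == length(times_s), length(fit_windows) == 2L)
  rng <- range(times_s)
  for (w in fit_windows)
    if (w[1] < rng[1] || w[2] > rng[2])
      stop("bleach-fit window [", w[1], ", ", w[2],
           "] outside the recording")
  base_sel <- times_s >= puff_onset_s - baseline_s & times_s < puff_onset_s
  stopifnot(sum(base_sel) >= 2)
  F0 <- mean(F[base_sel])
  if (F0 <= 0) stop("non-positive baseline fluorescence")
  dff <- (F - F0) / F0

  fit_sel <- (times_s >= fit_windows[[1]][1] & times_s <= fit_windows[[1]][2]) |
             (times_s >= fit_windows[[2]][1] & times_s <= fit_windows[[2]][2])
  basis <- splines::ns(times_s, df = spline_df,
                       Boundary.knots = range(times_s))
  fit <- stats::lm.fit(cbind(1, basis[fit_sel, , drop = FALSE]),
                       dff[fit_sel])
  bleach <- as.vector(cbind(1, basis) %*% fit$coefficients)
  corrected <- dff - bleach

  b <- corrected[base_sel]
  sd_b <- stats::sd(b)
  if (!is.finite(sd_b) || sd_b == 0) sd_b <- 1
  z <- (corrected - mean(b)) / sd_b
  post <- times_s >= puff_onset_s
  pk <- which.max(z[post])
  list(z = z, dff_corrected = corrected, bleach_fit = bleach,
       peak = max(z[post]), peak_time_s = times_s[post][pk])
}
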