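#' Ground-truth quadrat layout for synthetic movies
#'
#' Assigns one response type to every cell of the imaging grid, with optional
#' linear proportion gradients along the mediolateral (columns) and
#' anteroposterior (rows) axes, and defines the static field properties
#' (edge vignetting of baseline fluorescence, photobleaching rate, raw
#' baseline level, and the delta-F/F amplitude corresponding to one baseline
#' SD of response).
#'
#' Type proportions at grid position (row r, col c) are
#' `base + ml_gradient * u(c) + ap_gradient * v(r)` with `u`, `v` the
#' normalized axis positions in \[-0.5, 0.5\], clipped at zero and
#' renormalized; the configuration is rejected if any type's proportion
#' leaves \[0, 1\] at an axis extreme.
#'
#' @param grid_shape c(rows, cols), default 15 x 15
#' @param templates_R,templates_NR named lists of [response_template()] used
#'   for rewarded / unrewarded outcomes; a `"none"` entry may be `NULL`
#'   (non-responsive quadrats)
#' @param base_props named numeric vector of baseline type proportions over
#'   `names(templates_R)`, summing to 1
#' @param ml_gradient,ap_gradient named numeric vectors (or single 0) of
#'   per-type proportion change across the full axis span
#' @param f0 raw baseline fluorescence at the field centre (a.u.)
#' @param dff_per_z delta-F/F amplitude corresponding to 1 z of response
#' @param vignette_strength fractional F0 attenuation at the field corner,
#'   in \[0, 1)
#' @param bleach_rate per-frame exponential decay constant (0 = no bleaching)
#' @param seed integer seed for the type assignment
#' @return a `quadrat_layout` object; `$type` is a rows x cols character
#'   matrix of type names
#' @export
quadrat_layout <- function(grid_shape = c(15, 15),
                           templates_R = default_templates("R"),
                           templates_NR = default_templates("NR"),
                           base_props = c("pause" = 0.601,
                                          "burst-pause" = 0.082,
                                          "pause-burst" = 0.082,
                                          "increase" = 0.023,
                                          "none" = 0.212),
                           ml_gradient = 0, ap_gradient = 0,
                           f0 = 1000, dff_per_z = 0.02,
                           vignette_strength = 0.4, bleach_rate = 0,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1),
            abs(sum(base_props) - 1) < 1e-8, all(base_props >= 0),
            f0 > 0, dff_per_z > 0,
            vignette_strength >= 0, vignette_strength < 1, bleach_rate >= 0)
  types <- names(base_props)
  if (!all(setdiff(types, "none") %in% names(templates_R)))
    stop("every non-'none' type needs a reward template")
  expand_grad <- function(g) {
    if (length(g) == 1L && is.null(names(g)))
      g <- stats::setNames(rep(g, length(types)), types)
    out <- stats::setNames(numeric(length(types)), types)
    out[names(g)] <- g
    out
  }
  mlg <- expand_grad(ml_gradient)
  apg <- expand_grad(ap_gradient)
  # proportions must stay in [0,1] at the axis extremes
  for (ty in types) {
    p_ext <- base_props[ty] + c(-0.5, 0.5) * mlg[ty] +
      rep(c(-0.5, 0.5) * apg[ty], each = 2)
    if (any(p_ext < -1e-9) || any(p_ext > 1 + 1e-9))
      stop("type proportion for '", ty, "' leaves [0, 1] at an axis extreme")
  }
  nr <- grid_shape[1]; nc <- grid_shape[2]
  u <- if (nc > 1) (seq_len(nc) - (nc + 1) / 2) / (nc - 1) else 0
  v <- if (nr > 1) (seq_len(nr) - (nr + 1) / 2) / (nr - 1) else 0
  set.seed(seed)
  type <- matrix("", nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    p <- pmax(base_props + mlg * u[c] + apg * v[r], 0)
    type[r, c] <- sample(types, 1L, prob = p / sum(p))
  }
  structure(list(grid_shape = grid_shape, type = type,
                 templates_R = templates_R, templates_NR = templates_NR,
                 base_props = base_props, ml_gradient = mlg,
                 ap_gradient = apg, f0 = f0, dff_per_z = dff_per_z,
                 vignette_strength = vignette_strength,
                 bleach_rate = bleach_rate, seed = seed),
            class = "quadrat_layout")
}

#' @export
print.quadrat_layout <- function(x, ...) {
  cat(sprintf("quadrat_layout %d x %d (%d quadrats)\n",
              x$grid_shape[1], x$grid_shape[2], prod(x$grid_shape)))
  print(table(x$type))
  invisible(x)
}

#' Radial vignetting profile over a frame
#'
#' Multiplicative baseline attenuation increasing toward the field edge,
#' emulating the fall-off of baseline fluorescence under a GRIN lens:
#' `1 - strength * (r / r_corner)^2` with r the distance from the frame
#' centre. Always in (0, 1].
#'
#' @param dims c(H, W) in pixels
#' @param strength fractional attenuation at the corner, in \[0, 1)
#' @return H x W matrix in (0, 1]
#' @export
vignette_profile <- function(dims, strength = 0.4) {
  stopifnot(strength >= 0, strength < 1)
  H <- dims[1]; W <- dims[2]
  ry <- (seq_len(H) - (H + 1) / 2) / (H / 2)
  rx <- (seq_len(W) - (W + 1) / 2) / (W / 2)
  r2 <- outer(ry^2, rx^2, `+`) / 2  # corner -> ~1
  1 - strength * r2
}

#' Generate a synthetic two-photon movie with known ground truth
#'
#' Builds a T x H x W fluorescence stack (stored as an H x W x T array) in
#' which each grid quadrat carries its layout-assigned outcome-response
#' template at every trial outcome. Each pixel is
#' `vignette * F0 * (1 + dff(t)) * bleach(t) + N(0, noise_sd)`, where
#' `dff(t) = dff_per_z * template_z(t - outcome)` summed over trials, and an
#' optional integer-pixel motion jitter translates whole frames (border
#' filled with the frame median). An optional second, acetylcholine-
#' insensitive channel carries the static baseline plus noise only
#' (emulating a co-expressed static red fluorophore).
#'
#' @param layout a [quadrat_layout()]
#' @param trials data.frame with columns `outcome` ("R"/"NR") and
#'   `outcome_time_s`
#' @param dims frame size c(H, W); must be divisible by the grid
#' @param frame_rate Hz
#' @param duration_s total length; default covers the last outcome + 2 s
#' @param noise_sd pixel Gaussian noise SD in raw intensity units
#' @param texture_sd SD of the static multiplicative spatial texture
#'   (relative units) emulating tissue structure (somata/neuropil) in the
#'   field; constant over time, so it cancels in delta-F/F, but it anchors
#'   translation registration
#' @param jitter_px maximum |shift| of the random per-frame jitter (0 = none)
#' @param jitter_schedule optional T x 2 integer matrix (dy, dx) overriding
#'   the random schedule
#' @param control_channel also simulate the ACh-insensitive channel
#' @param seed integer seed
#' @return list with `movie` (`ach_movie`: `$frames` H x W x T, `$frame_rate`),
#'   `truth` (per-quadrat data.frame: grid position, type, template
#'   amplitude/latency per outcome, mean vignetted F0), `shifts` (T x 2
#'   applied (dy, dx)), `dff` (n_quadrat x T ground-truth delta-F/F),
#'   and optionally `control` (`ach_movie`)
#' @export
generate_movie <- function(layout, trials, dims = c(150, 150),
                           frame_rate = 30, duration_s = NULL,
                           noise_sd = 0, texture_sd = 0.15, jitter_px = 0,
                           jitter_schedule = NULL,
                           control_channel = FALSE, seed = 1L) {
  stopifnot(inherits(layout, "quadrat_layout"),
            is.data.frame(trials),
            all(c("outcome", "outcome_time_s") %in% names(trials)))
  H <- dims[1]; W <- dims[2]
  nr <- layout$grid_shape[1]; nc <- layout$grid_shape[2]
  if (H %% nr != 0 || W %% nc != 0)
    stop("frame dims ", H, "x", W, " not divisible by grid ", nr, "x", nc)
  if (is.null(duration_s))
    duration_s <- max(trials$outcome_time_s) + 2
  T_ <- round(duration_s * frame_rate)
  tt <- (seq_len(T_) - 1) / frame_rate
  set.seed(seed)

  # ground-truth delta-F/F per quadrat (row-major over grid: quadrat index
  # q = (col-1)*nr + row, i.e. column-major like R matrices)
  nq <- nr * nc
  dff <- matrix(0, nq, T_)
  for (q in seq_len(nq)) {
    ty <- layout$type[q]
    if (ty == "none") next
    for (i in seq_len(nrow(trials))) {
      tmpl <- if (trials$outcome[i] == "R") layout$templates_R[[ty]]
              else layout$templates_NR[[ty]]
      if (is.null(tmpl)) next
      rel <- tt - trials$outcome_time_s[i]
      sel <- rel >= 0 & rel < tmpl$duration_s
      if (any(sel))
        dff[q, sel] <- dff[q, sel] +
          layout$dff_per_z * template_eval(tmpl, rel[sel])
    }
  }

  vig <- vignette_profile(dims, layout$vignette_strength)
  base <- vig * layout$f0
  if (texture_sd > 0)
    base <- base * pmax(1 + matrix(stats::rnorm(H * W, 0, texture_sd),
                                   H, W), 0.05)
  bleach <- exp(-layout$bleach_rate * (seq_len(T_) - 1))
  rowmap <- rep(seq_len(nr), each = H / nr)
  colmap <- rep(seq_len(nc), each = W / nc)

  if (is.null(jitter_schedule)) {
    shifts <- if (jitter_px > 0)
      cbind(sample(-jitter_px:jitter_px, T_, replace = TRUE),
            sample(-jitter_px:jitter_px, T_, replace = TRUE))
    else matrix(0L, T_, 2)
  } else {
    stopifnot(nrow(jitter_schedule) == T_, ncol(jitter_schedule) == 2)
    shifts <- jitter_schedule
  }

  frames <- array(0, dim = c(H, W, T_))
  ctrl <- if (control_channel) array(0, dim = c(H, W, T_)) else NULL
  for (t in seq_len(T_)) {
    dmat <- matrix(dff[, t], nr, nc)
    fr <- base * (1 + dmat[cbind(rep(rowmap, times = W),
                                 rep(colmap, each = H))] * 1) * bleach[t]
    dim(fr) <- c(H, W)
    if (noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
    frames[, , t] <- shift_frame(fr, shifts[t, 1], shifts[t, 2])
    if (control_channel) {
      cf <- base
      if (noise_sd > 0)
        cf <- cf + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
      ctrl[, , t] <- shift_frame(cf, shifts[t, 1], shifts[t, 2])
    }
  }

  q_row <- rep(seq_len(nr), times = nc)
  q_col <- rep(seq_len(nc), each = nr)
  tparam <- function(tl, q) {
    ty <- layout$type[q]
    if (ty == "none" || is.null(tl[[ty]])) c(NA_real_, NA_real_)
    else c(tl[[ty]]$amplitude, tl[[ty]]$extremum_latency_s)
  }
  pr <- t(vapply(seq_len(nq), function(q) tparam(layout$templates_R, q),
                 numeric(2)))
  pn <- t(vapply(seq_len(nq), function(q) tparam(layout$templates_NR, q),
                 numeric(2)))
  f0q <- as.vector(block_mean(base, nr, nc))
  truth <- data.frame(quadrat = seq_len(nq), grid_row = q_row,
                      grid_col = q_col, type = as.vector(layout$type),
                      amplitude_R = pr[, 1], latency_R = pr[, 2],
                      amplitude_NR = pn[, 1], latency_NR = pn[, 2],
                      f0 = f0q, dff_per_z = layout$dff_per_z)

  out <- list(movie = ach_movie(frames, frame_rate), truth = truth,
              shifts = shifts, dff = dff)
  if (control_channel) out$control <- ach_movie(ctrl, frame_rate)
  out
}

#' Movie container
#'
#' @param frames H x W x T numeric array of non-negative intensities
#' @param frame_rate Hz
#' @return an `ach_movie` object
#' @export
ach_movie <- function(frames, frame_rate = 30) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] >= 2,
            frame_rate > 0)
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "ach_movie")
}

#' @export
print.ach_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("ach_movie: %d x %d px, %d frames @ %g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$frame_rate, d[3] / x$frame_rate))
  invisible(x)
}

# integer translation of a matrix by (dy, dx), median fill at the border
shift_frame <- function(m, dy, dx) {
  if (dy == 0 && dx == 0) return(m)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(stats::median(m), H, W)
  src_r <- seq_len(H) - dy
  src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# mean of each grid block of a matrix -> nr x nc matrix
block_mean <- function(m, nr, nc) {
  H <- nrow(m); W <- ncol(m)
  Pr <- matrix(0, nr, H)
  Pr[cbind(rep(seq_len(nr), each = H / nr), seq_len(H))] <- nr / H
  Pc <- matrix(0, nc, W)
  Pc[cbind(rep(seq_len(nc), each = W / nc), seq_len(W))] <- nc / W
  Pr %*% m %*% t(Pc)
}

#' Read and write movies as multi-page TIFF
#'
#' Frames are stored float32, one page per frame, intensities rescaled to
#' \[0, 1\] by the recorded maximum (stored in the description is not
#' portable, so the scale is returned alongside).
#'
#' @param movie an [ach_movie()]
#' @param path file path
#' @param frame_rate frame rate to attach on read
#' @return `write_movie_tiff` returns the intensity scale used (max value);
#'   `read_movie_tiff` returns an `ach_movie` (intensities on the stored
#'   \[0, 1\] scale unless `scale` is given)
#' @export
write_movie_tiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  stopifnot(inherits(movie, "ach_movie"))
  mx <- max(movie$frames)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(movie$frames)[3]),
                  function(t) movie$frames[, , t] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(mx)
}

#' @rdname write_movie_tiff
#' @param scale multiply stored intensities by this factor
#' @export
read_movie_tiff <- function(path, frame_rate = 30, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]] * scale
  ach_movie(frames, frame_rate)
}
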