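#' Implant metadata for anatomical quadrat mapping
#'
#' @param ml_center mediolateral implant centre, mm from midline
#' @param ap_center anteroposterior implant centre, mm from bregma
#'   (anterior positive)
#' @param mirror_ml,mirror_ap flip the respective axis (GRIN-lens optical
#'   inversion)
#' @param spacing_mm physical spacing per quadrat, default 0.05 mm (~50 µm)
#' @param scale uniform scaling factor, default 1
#' @return an `implant_meta` object
#' @export
implant_meta <- function(ml_center, ap_center, mirror_ml = FALSE,
                         mirror_ap = FALSE, spacing_mm = 0.05, scale = 1) {
  stopifnot(spacing_mm > 0, scale > 0)
  structure(list(ml_center = ml_center, ap_center = ap_center,
                 mirror_ml = mirror_ml, mirror_ap = mirror_ap,
                 spacing_mm = spacing_mm, scale = scale),
            class = "implant_meta")
}

#' Anatomical coordinates and region of a quadrat
#'
#' Maps grid indices to mediolateral/anteroposterior coordinates:
#' `offset = (index - centre_index) * spacing * scale`, sign-flipped by the
#' mirror flags, added to the implant centre. The centre index of a
#' 15-grid is its midpoint cell, 8, so offsets span +/-7 quadrats
#' (+/-0.35 mm at the default spacing). Columns map to ML, rows to AP
#' (row 1 anterior, i.e. the AP offset decreases with increasing row).
#' Quadrats with both row and column in 3-13 are `central`; those with a
#' row or column in 1-2 or 14-15 are `peripheral`.
#'
#' @param grid_row,grid_col 1-based grid indices (vectorised)
#' @param meta an [implant_meta()]
#' @param grid_shape c(rows, cols), default 15 x 15
#' @return data.frame with `grid_row`, `grid_col`, `ml_mm`, `ap_mm`,
#'   `region`
#' @export
quadrat_coords <- function(grid_row, grid_col, meta,
                           grid_shape = c(15, 15)) {
  stopifnot(inherits(meta, "implant_meta"),
            length(grid_row) == length(grid_col))
  if (any(grid_row < 1 | grid_row > grid_shape[1] |
          grid_col < 1 | grid_col > grid_shape[2]))
    stop("grid index outside the ", grid_shape[1], " x ", grid_shape[2],
         " grid")
  c_row <- (grid_shape[1] + 1) %/% 2
  c_col <- (grid_shape[2] + 1) %/% 2
  step <- meta$spacing_mm * meta$scale
  sml <- if (meta$mirror_ml) -1 else 1
  sap <- if (meta$mirror_ap) -1 else 1
  ml <- meta$ml_center + sml * (grid_col - c_col) * step
  ap <- meta$ap_center + sap * (c_row - grid_row) * step
  lo <- 3; hi_r <- grid_shape[1] - 2; hi_c <- grid_shape[2] - 2
  region <- ifelse(grid_row >= lo & grid_row <= hi_r &
                   grid_col >= lo & grid_col <= hi_c,
                   "central", "peripheral")
  data.frame(grid_row = grid_row, grid_col = grid_col,
             ml_mm = ml, ap_mm = ap, region = region)
}

#' Proportion gradient of response types along an anatomical axis
#'
#' Bins quadrats along one grid axis (one bin per row/column by default),
#' computes each response type's proportion per bin, and regresses the
#' proportion on the bin's axis coordinate by least squares, reporting the
#' slope (proportion per mm), Pearson r and the slope P value per type.
#' Empty bins are dropped.
#'
#' @param labels character vector of response-type labels per quadrat
#' @param axis_mm numeric axis coordinate per quadrat (e.g. `ml_mm`)
#' @param n_bins number of equal-width bins; default one bin per distinct
#'   coordinate value when they are few (grid columns), else 15
#' @return data.frame with one row per type: `type`, `slope`, `r`,
#'   `p_value`, `n_bins`
#' @export
axis_proportion_regression <- function(labels, axis_mm, n_bins = NULL) {
  stopifnot(length(labels) == length(axis_mm))
  vals <- sort(unique(axis_mm))
  if (is.null(n_bins)) n_bins <- if (length(vals) <= 15) length(vals) else 15
  if (length(vals) <= n_bins) {
    bin <- match(axis_mm, vals)
    centers <- vals
  } else {
    breaks <- seq(min(axis_mm), max(axis_mm), length.out = n_bins + 1)
    bin <- cut(axis_mm, breaks, include.lowest = TRUE, labels = FALSE)
    centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  }
  keep_bins <- sort(unique(bin))
  if (length(keep_bins) < 3)
    stop("axis regression needs at least 3 non-empty bins")
  types <- sort(unique(labels))
  out <- lapply(types, function(ty) {
    prop <- vapply(keep_bins, function(b) mean(labels[bin == b] == ty),
                   numeric(1))
    x <- centers[keep_bins]
    if (stats::sd(prop) == 0) {
      data.frame(type = ty, slope = 0, r = NA_real_, p_value = NA_real_,
                 n_bins = length(keep_bins))
    } else {
      fit <- stats::lm(prop ~ x)
      sm <- summary(fit)
      data.frame(type = ty, slope = stats::coef(fit)[2],
                 r = stats::cor(x, prop),
                 p_value = sm$coefficients[2, 4],
                 n_bins = length(keep_bins))
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare central and peripheral quadrat responses
#'
#' Mean outcome-evoked z per region and a two-sample Student's t-test of
#' the difference. For the default 15 x 15 grid the regions partition the
#' 225 quadrats into 121 central and 104 peripheral.
#'
#' @param z_stat numeric response statistic per quadrat
#' @param region character vector, `"central"` / `"peripheral"`
#' @return list with `mean_central`, `mean_peripheral`, `n_central`,
#'   `n_peripheral`, `test` (a [t_test()] result, or NULL when either
#'   region has fewer than 2 quadrats)
#' @export
central_peripheral_compare <- function(z_stat, region) {
  stopifnot(length(z_stat) == length(region),
            all(region %in% c("central", "peripheral")))
  zc <- z_stat[region == "central"]
  zp <- z_stat[region == "peripheral"]
  if (length(zc) == 0 || length(zp) == 0)
    stop("both regions must be non-empty")
  tst <- if (length(zc) >= 2 && length(zp) >= 2)
    t_test(zc, zp, paired = FALSE) else NULL
  list(mean_central = mean(zc), mean_peripheral = mean(zp),
       n_central = length(zc), n_peripheral = length(zp), test = tst)
}

#' Baseline-fluorescence dependence control
#'
#' Pearson correlation between per-quadrat baseline fluorescence (F0) and
#' the mean behavior-linked response, to check that edge vignetting of the
#' baseline does not leak into the response statistics.
#'
#' @param f0 baseline fluorescence per quadrat
#' @param mean_z mean evoked z per quadrat
#' @return list with `r`, `p_value`, `n`; both NA (flagged via `defined =
#'   FALSE`) for degenerate input (n < 3 or zero variance)
#' @export
f0_dependence <- function(f0, mean_z) {
  stopifnot(length(f0) == length(mean_z))
  n <- length(f0)
  if (n < 3 || stats::sd(f0) == 0 || stats::sd(mean_z) == 0) {
    warning("degenerate input: correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  }
  pr <- pearson_r(f0, mean_z)
  list(r = pr$r, p_value = pr$p_value, n = n, defined = TRUE)
}
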