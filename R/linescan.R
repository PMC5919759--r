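# RBC velocimetry from line scans, FWHM lumen diameters, and laminar flux.

#' Construct a line-scan image
#'
#' A line-scan image is a lines x pixels intensity grid from repeated 1D
#' scanning along a vessel axis, with its physical calibration: the time
#' per line (ms) and the spatial pixel pitch (um). Moving RBCs exclude the
#' plasma dye and trace dark diagonal streaks; the streak slope in
#' (time, distance) coordinates is dt/dx, and RBC velocity is its
#' reciprocal.
#'
#' @param img Numeric matrix, rows = lines (time), columns = pixels (space).
#' @param line_period_ms Time per line, ms (> 0).
#' @param pixel_pitch_um Spatial calibration, um/pixel (> 0).
#' @return A `linescan_image` object.
#' @export
linescan_image <- function(img, line_period_ms, pixel_pitch_um) {
  stopifnot(is.matrix(img), line_period_ms > 0, pixel_pitch_um > 0)
  structure(list(img = img, line_period_ms = line_period_ms,
                 pixel_pitch_um = pixel_pitch_um),
            class = "linescan_image")
}

#' @export
print.linescan_image <- function(x, ...) {
  cat(sprintf("linescan: %d lines x %d pixels, %.4g ms/line, %.3g um/pixel\n",
              nrow(x$img), ncol(x$img), x$line_period_ms, x$pixel_pitch_um))
  invisible(x)
}

# Straightness of a (line, center) trajectory. R^2 of the linear fit; a
# zero-variance (vertical streak, v = 0) trajectory is perfectly straight.
.streak_r2 <- function(line, center) {
  if (length(line) < 3) return(1)
  fit <- stats::lm(center ~ line)
  tss <- sum((center - mean(center))^2)
  if (tss < 1e-10) return(1)
  1 - sum(stats::residuals(fit)^2) / tss
}

# Fit one streak trajectory; returns slope in px/line plus straightness.
.fit_streak <- function(line, center) {
  if (length(line) < 2) return(NULL)
  slope <- if (length(unique(line)) < 2) NA_real_ else
    unname(stats::coef(stats::lm(center ~ line))[2])
  list(slope_px_per_line = slope, r2 = .streak_r2(line, center))
}

# Shear rows of the dip image by -dpx per line and average them; streaks
# aligned at the true displacement collapse into sharp peaks, so the
# variance of the aligned profile scores the candidate orientation.
.aligned_profile <- function(D, dpx) {
  n_lines <- nrow(D); n_px <- ncol(D)
  px <- seq_len(n_px)
  acc <- matrix(NA_real_, n_lines, n_px)
  for (j in seq_len(n_lines)) {
    shift <- dpx * (j - 1)
    acc[j, ] <- stats::approx(px - shift, D[j, ], xout = px, rule = 1)$y
  }
  colMeans(acc, na.rm = TRUE)
}

.sweep_dpx <- function(D, grid) {
  scores <- vapply(grid, function(d) {
    p <- .aligned_profile(D, d)
    stats::var(p, na.rm = TRUE)
  }, numeric(1))
  grid[which.max(scores)]
}

#' Estimate RBC velocity from a line-scan image
#'
#' Measures the slope of RBC streaks. Each streak's slope in (time,
#' distance) coordinates is dt/dx (ms/um); velocity is its reciprocal,
#' averaged over streaks. Streaks can be supplied manually (as traced
#' points, mirroring human raters) or detected automatically by
#' dominant-orientation search on the contrast-inverted image followed by
#' per-streak trajectory fits. Curvilinear streaks (linear-fit R^2 below
#' `r2_threshold`) are excluded; a scan with no detectable streaks is
#' flagged as no-flow rather than reported as zero velocity.
#'
#' @param img A [linescan_image()], or a list of them from repeated scans
#'   of the same vessel (streak velocities are pooled before averaging).
#' @param streaks Optional manual streaks: data frame with columns
#'   `streak`, `line`, `pixel` (>= 2 points per streak).
#' @param n_streaks Number of equally spaced streaks to measure per scan in
#'   automatic mode (the protocol used 3).
#' @param r2_threshold Straightness cutoff below which a streak is
#'   excluded as curvilinear.
#' @param max_dpx Largest streak displacement searched, px/line.
#' @return A `velocity_estimate`: `v` (um/s, >= 0), `slopes_ms_per_um`
#'   (signed per-streak inverse slopes), `n_streaks`, `flow_direction`
#'   (+1/-1/0), `no_flow` flag, and `n_excluded`.
#' @export
estimate_rbc_velocity <- function(img, streaks = NULL, n_streaks = 3,
                                  r2_threshold = 0.9, max_dpx = 4) {
  if (is.list(img) && !inherits(img, "linescan_image")) {
    streak_list <- if (is.null(streaks) || is.data.frame(streaks)) {
      rep(list(streaks), length(img))
    } else {
      stopifnot(length(streaks) == length(img))
      streaks
    }
    per_scan <- Map(function(im, st) {
      estimate_rbc_velocity(im, streaks = st, n_streaks = n_streaks,
                            r2_threshold = r2_threshold, max_dpx = max_dpx)
    }, img, streak_list)
    slopes <- unlist(lapply(per_scan, function(e) e$slopes_ms_per_um))
    if (!length(slopes)) {
      return(structure(list(v = NA_real_, slopes_ms_per_um = numeric(0),
                            n_streaks = 0L, flow_direction = 0,
                            no_flow = TRUE, n_excluded = 0L),
                       class = "velocity_estimate"))
    }
    return(.velocity_from_slopes(slopes,
                                 sum(vapply(per_scan, function(e) e$n_excluded,
                                            integer(1)))))
  }
  stopifnot(inherits(img, "linescan_image"))
  lp <- img$line_period_ms; pp <- img$pixel_pitch_um
  if (!is.null(streaks)) {
    stopifnot(all(c("streak", "line", "pixel") %in% names(streaks)))
    fits <- lapply(split(streaks, streaks$streak),
                   function(s) .fit_streak(s$line, s$pixel))
  } else {
    fits <- .detect_streaks(img$img, n_streaks = n_streaks, max_dpx = max_dpx)
    if (is.null(fits)) {
      return(structure(list(v = NA_real_, slopes_ms_per_um = numeric(0),
                            n_streaks = 0L, flow_direction = 0,
                            no_flow = TRUE, n_excluded = 0L),
                       class = "velocity_estimate"))
    }
  }
  fits <- Filter(function(f) !is.null(f) && !is.na(f$slope_px_per_line), fits)
  keep <- vapply(fits, function(f) f$r2 >= r2_threshold, logical(1))
  n_excluded <- sum(!keep)
  fits <- fits[keep]
  if (!length(fits)) {
    return(structure(list(v = NA_real_, slopes_ms_per_um = numeric(0),
                          n_streaks = 0L, flow_direction = 0,
                          no_flow = TRUE, n_excluded = n_excluded),
                     class = "velocity_estimate"))
  }
  slope_px <- vapply(fits, function(f) f$slope_px_per_line, numeric(1))
  # inverse slope dt/dx in ms/um; infinite for vertical (v = 0) streaks
  slopes_ms_per_um <- ifelse(slope_px == 0, Inf, lp / (slope_px * pp))
  .velocity_from_slopes(slopes_ms_per_um, n_excluded)
}

.velocity_from_slopes <- function(slopes_ms_per_um, n_excluded = 0L) {
  v_each <- ifelse(is.infinite(slopes_ms_per_um), 0,
                   1000 / abs(slopes_ms_per_um))
  dirs <- sign(slopes_ms_per_um)
  dirs[is.infinite(slopes_ms_per_um)] <- 0
  structure(list(v = mean(v_each),
                 slopes_ms_per_um = slopes_ms_per_um,
                 n_streaks = length(slopes_ms_per_um),
                 flow_direction = sign(sum(dirs)),
                 no_flow = FALSE,
                 n_excluded = as.integer(n_excluded)),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  if (x$no_flow) {
    cat("velocity estimate: NO FLOW (no usable streaks)\n")
  } else {
    cat(sprintf("velocity estimate: %.1f um/s (%d streaks, direction %+d)\n",
                x$v, x$n_streaks, x$flow_direction))
  }
  invisible(x)
}

# Automatic streak detection: dominant orientation by shear-and-project
# variance sweep, then per-streak trajectory extraction around the aligned
# peaks. Returns NULL when the image holds no detectable streaks.
.detect_streaks <- function(M, n_streaks = 3, max_dpx = 4) {
  bg <- stats::median(M)
  D <- pmax(bg - M, 0)
  rng <- diff(range(M))
  noise <- stats::mad(M - bg)
  # no appreciable dark structure at all -> obstructed scan
  if (rng <= 0 || max(D) < max(6 * noise, 0.05 * max(abs(M))))
    return(NULL)
  coarse <- seq(-max_dpx, max_dpx, by = 0.1)
  d1 <- .sweep_dpx(D, coarse)
  fine <- seq(d1 - 0.1, d1 + 0.1, by = 0.005)
  dpx <- .sweep_dpx(D, fine)
  prof <- .aligned_profile(D, dpx)
  peak_floor <- max(max(prof, na.rm = TRUE) * 0.5,
                    6 * noise / sqrt(nrow(M)))
  n_px <- ncol(M)
  is_peak <- which(
    prof >= peak_floor &
      prof >= c(-Inf, prof[-n_px]) & prof >= c(prof[-1], -Inf))
  if (!length(is_peak)) return(NULL)
  # merge adjacent peak pixels
  grp <- cumsum(c(1, diff(is_peak) > 2))
  centers0 <- vapply(split(is_peak, grp),
                     function(ix) ix[which.max(prof[ix])], numeric(1))
  # pick equally spaced streaks, as in the manual protocol
  if (length(centers0) > n_streaks) {
    centers0 <- centers0[round(seq(1, length(centers0), length.out = n_streaks))]
  }
  w <- max(2, round(2 * abs(dpx)) + 3)
  n_lines <- nrow(M)
  fits <- lapply(centers0, function(c0) {
    line_idx <- c(); cent <- c()
    for (j in seq_len(n_lines)) {
      pred <- c0 + dpx * (j - 1)
      lo <- max(1, floor(pred - w)); hi <- min(n_px, ceiling(pred + w))
      if (lo > hi) next
      seg <- D[j, lo:hi]
      if (max(seg) < 3 * noise) next
      wt <- pmax(seg - 0.25 * max(seg), 0)
      if (sum(wt) == 0) next
      line_idx <- c(line_idx, j)
      cent <- c(cent, sum((lo:hi) * wt) / sum(wt))
    }
    .fit_streak(line_idx, cent)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) NULL else fits
}

#' Fit a lumen diameter as the FWHM of a Gaussian intensity profile
#'
#' Least-squares fit of a Gaussian plus constant baseline to a 1D
#' intensity profile drawn perpendicular to the vessel; the diameter is
#' the full width at half maximum, `2 * sqrt(2 * log(2)) * sigma`.
#'
#' @param intensity Numeric profile values.
#' @param position_um Positions (um) of the samples; defaults to a 1-um
#'   grid.
#' @return A `diameter_estimate`: `fwhm` (um), `amplitude`, `center`,
#'   `sigma`, `baseline`.
#' @export
fit_fwhm_diameter <- function(intensity, position_um = seq_along(intensity) - 1) {
  stopifnot(length(intensity) == length(position_um), length(intensity) >= 5)
  y <- as.numeric(intensity); x <- as.numeric(position_um)
  if (diff(range(y)) <= 0) stop("flat profile: no peak to fit")
  b0 <- min(y); a0 <- max(y) - b0
  m0 <- x[which.max(y)]
  wts <- pmax(y - b0, 0)
  s0 <- sqrt(sum(wts * (x - m0)^2) / sum(wts))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 10
  sse <- function(p) {
    pred <- p[4] + p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2))
    sum((y - pred)^2)
  }
  fit <- try(stats::optim(c(a0, m0, s0, b0), sse, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) {
    stop("Gaussian fit failed on this profile")
  }
  # reject fits that explain none of the profile's structure
  if (fit$value > 0.95 * sum((y - mean(y))^2)) {
    stop("Gaussian fit failed on this profile")
  }
  cf <- c(a = fit$par[1], m = fit$par[2], s = fit$par[3], b = fit$par[4])
  sigma <- abs(unname(cf["s"]))
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  if (!(fwhm > 0)) stop("Gaussian fit collapsed to zero width")
  structure(list(fwhm = fwhm, amplitude = unname(cf["a"]),
                 center = unname(cf["m"]), sigma = sigma,
                 baseline = unname(cf["b"])),
            class = "diameter_estimate")
}

#' @export
print.diameter_estimate <- function(x, ...) {
  cat(sprintf("diameter (FWHM): %.3f um (sigma = %.3f um)\n", x$fwhm, x$sigma))
  invisible(x)
}

#' RBC flux under laminar flow
#'
#' `F = (pi / 8) * v * d^2`: the volume of blood traversing a vessel per
#' second given centerline RBC velocity `v` and lumen diameter `d`.
#'
#' @param v RBC velocity, um/s (>= 0).
#' @param d Lumen diameter, um (> 0).
#' @return A `flux_estimate`: `flux` (um^3/s), `v`, `d`.
#' @export
rbc_flux <- function(v, d) {
  if (any(v < 0)) stop("velocity must be >= 0")
  if (any(d <= 0)) stop("diameter must be > 0")
  structure(list(flux = (pi / 8) * v * d^2, v = v, d = d),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("RBC flux: %.1f um^3/s (v = %.1f um/s, d = %.2f um)\n",
              x$flux, x$v, x$d))
  invisible(x)
}

#' Normalize a hemodynamic time course to its baseline
#'
#' Divides each value by the baseline value so the baseline maps to 1.0,
#' as used for per-vessel velocity/flux time courses.
#'
#' @param values Numeric series, one value per timepoint.
#' @param baseline_index Index of the baseline timepoint (default first).
#' @return Numeric series of the same length.
#' @export
normalize_timecourse <- function(values, baseline_index = 1) {
  stopifnot(baseline_index >= 1, baseline_index <= length(values))
  b <- values[baseline_index]
  if (!is.finite(b) || b == 0) stop("baseline value must be nonzero")
  values / b
}
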