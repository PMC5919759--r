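# Vascular immunosignal coverage at obstruction sites, population
# classification by a coverage cutoff, and perivascular nuclei counting.

# Binarize a channel for coverage scoring: radius-2 median filter then
# auto-threshold. Logical input is taken as an already-binarized mask.
.coverage_mask <- function(channel, method, median_radius = 2) {
  if (is.logical(channel)) return(channel)
  stopifnot(is.matrix(channel))
  filt <- median_filter(channel, median_radius)
  h <- hist_256(filt)
  lev <- auto_threshold(h, method = method)
  apply_threshold(filt, lev, lo = attr(h, "min"), hi = attr(h, "max"))
}

#' Percent signal coverage of the vasculature around a site
#'
#' Quantifies, inside a square ROI centered on an obstruction site, the
#' percentage of vessel-mask pixels that also carry immunosignal:
#' `coverage = 100 * (signal & vessel pixels) / vessel pixels`. Intensity
#' channels are median-filtered (radius 2) and auto-thresholded (Triangle
#' for the vessel channel, Yen by default for the signal channel);
#' already-binarized logical channels are used as-is. Restricting the
#' signal to the vessel mask is the set-intersection form of masking the
#' signal channel with the (inverted) vessel mask.
#'
#' @param vessel_channel,signal_channel Numeric matrices (intensities) or
#'   logical matrices (masks), co-registered.
#' @param site_center Length-2 site position `(x, y)` = (column, row) in
#'   pixels.
#' @param roi_halfwidth_um ROI half-width, um (default 15: the ROI spans
#'   15 um on either side of the site).
#' @param pixel_pitch_um Spatial calibration, um/pixel.
#' @param signal_method Auto-threshold method for the signal channel
#'   (`"yen"` default, `"moments"` available).
#' @param vessel_method Auto-threshold for the vessel channel.
#' @return A `coverage_result`: `pct_coverage` (NA and `flagged = TRUE`
#'   when the ROI holds no vessel pixels), `n_vessel_px`, `n_signal_px`,
#'   `roi_halfwidth_um`.
#' @export
vascular_coverage <- function(vessel_channel, signal_channel, site_center,
                              roi_halfwidth_um = 15, pixel_pitch_um = 1,
                              signal_method = "yen",
                              vessel_method = "triangle") {
  stopifnot(length(site_center) == 2, pixel_pitch_um > 0,
            all(dim(vessel_channel) == dim(signal_channel)))
  vmask <- .coverage_mask(vessel_channel, vessel_method)
  smask <- .coverage_mask(signal_channel, signal_method)
  hw <- roi_halfwidth_um / pixel_pitch_um
  cx <- site_center[1]; cy <- site_center[2]
  cols <- seq(ceiling(cx - hw), floor(cx + hw))
  rows <- seq(ceiling(cy - hw), floor(cy + hw))
  if (min(rows) < 1 || min(cols) < 1 ||
      max(rows) > nrow(vmask) || max(cols) > ncol(vmask)) {
    stop("ROI extends outside the image")
  }
  v <- vmask[rows, cols]
  s <- smask[rows, cols]
  n_vessel <- sum(v)
  n_signal <- sum(s & v)
  structure(list(
    pct_coverage = if (n_vessel > 0) 100 * n_signal / n_vessel else NA_real_,
    n_vessel_px = n_vessel, n_signal_px = n_signal,
    roi_halfwidth_um = roi_halfwidth_um,
    flagged = n_vessel == 0
  ), class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  if (x$flagged) {
    cat("coverage: undefined (no vessel pixels in ROI)\n")
  } else {
    cat(sprintf("coverage: %.1f%% of %d vessel pixels (ROI half-width %g um)\n",
                x$pct_coverage, x$n_vessel_px, x$roi_halfwidth_um))
  }
  invisible(x)
}

#' Classify coverage values into high and low populations
#'
#' Recanalized capillaries separate into two populations by vascular
#' immunosignal coverage; a value at or above the cutoff (default 20%) is
#' `"high"`, below it `"low"`. The boundary is assigned to `"high"`.
#'
#' @param coverages Numeric vector of percent coverages in `[0, 100]`.
#' @param cutoff Cutoff in percent (default 20).
#' @return Character vector of `"high"` / `"low"` labels.
#' @export
classify_population <- function(coverages, cutoff = 20) {
  if (!length(coverages)) return(character(0))
  if (any(coverages < 0 | coverages > 100, na.rm = TRUE)) {
    stop("coverages must be in [0, 100]")
  }
  ifelse(coverages >= cutoff, "high", "low")
}

#' Count endothelial nuclei near an obstruction site
#'
#' Counts nuclei whose footprint (a disk of `nucleus_radius_um`) lies
#' entirely on the vessel mask (complete colocalization with the
#' endothelial signal) and whose centroid is within `radius_um` of the
#' site.
#'
#' @param centroids Data frame with nucleus centroids `x_um`, `y_um`.
#' @param vessel_mask Logical matrix (rows = y, cols = x).
#' @param site_center_um Length-2 site position `(x, y)`, um.
#' @param radius_um Counting radius around the site, um (default 100).
#' @param pixel_pitch_um Calibration of the mask, um/pixel.
#' @param nucleus_radius_um Nucleus footprint radius, um.
#' @return A `nuclei_count`: `n`, `radius_um`.
#' @export
count_perivascular_nuclei <- function(centroids, vessel_mask, site_center_um,
                                      radius_um = 100, pixel_pitch_um = 1,
                                      nucleus_radius_um = 2) {
  stopifnot(is.logical(vessel_mask), is.matrix(vessel_mask),
            all(c("x_um", "y_um") %in% names(centroids)))
  n <- 0L
  if (nrow(centroids) > 0) {
    rpx <- nucleus_radius_um / pixel_pitch_um
    for (i in seq_len(nrow(centroids))) {
      cx <- centroids$x_um[i]; cy <- centroids$y_um[i]
      if (sqrt((cx - site_center_um[1])^2 + (cy - site_center_um[2])^2) >
          radius_um) next
      cxp <- cx / pixel_pitch_um; cyp <- cy / pixel_pitch_um
      cols <- seq(max(1, floor(cxp - rpx)),
                  min(ncol(vessel_mask), ceiling(cxp + rpx)))
      rows <- seq(max(1, floor(cyp - rpx)),
                  min(nrow(vessel_mask), ceiling(cyp + rpx)))
      g <- expand.grid(r = rows, c = cols)
      inside <- (g$c - cxp)^2 + (g$r - cyp)^2 <= rpx^2
      g <- g[inside, , drop = FALSE]
      if (nrow(g) == 0) next
      if (all(vessel_mask[cbind(g$r, g$c)])) n <- n + 1L
    }
  }
  structure(list(n = n, radius_um = radius_um), class = "nuclei_count")
}

#' @export
print.nuclei_count <- function(x, ...) {
  cat(sprintf("%d endothelial nuclei within %g um\n", x$n, x$radius_um))
  invisible(x)
}
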