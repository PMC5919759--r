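# Automated capillary census from fluorescence stacks: substack splitting,
# maximum projection, Triangle auto-thresholding, median despeckling,
# topological skeletonization, and conversion of vascular volume to a
# capillary count via the canonical single-capillary volume.

#' Construct a voxel stack
#'
#' A 3D intensity grid with its physical calibration. Axis order is
#' (x, y, z); the default z-step of 2 um matches in vivo acquisition.
#'
#' @param data 3D numeric array.
#' @param voxel_size_um Numeric length-3 voxel size (x, y, z), um.
#' @param channel Optional channel label.
#' @return A `voxel_stack` object.
#' @export
voxel_stack <- function(data, voxel_size_um = c(0.62, 0.62, 2), channel = "") {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(voxel_size_um) == 3, all(voxel_size_um > 0))
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 channel = channel),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel stack: %d x %d x %d voxels at %.3g x %.3g x %.3g um%s\n",
              d[1], d[2], d[3], x$voxel_size_um[1], x$voxel_size_um[2],
              x$voxel_size_um[3],
              if (nzchar(x$channel)) paste0(" [", x$channel, "]") else ""))
  invisible(x)
}

#' Split a stack into consecutive substacks
#'
#' Consecutive, non-overlapping groups of `n_slices` z-planes (default 10,
#' i.e. 20 um at a 2-um z-step). A final partial group is retained and its
#' true physical depth tracked.
#'
#' @param stack A [voxel_stack()].
#' @param n_slices Slices per substack.
#' @return List of `voxel_stack` objects, each with attribute `depth_um`.
#' @export
split_substacks <- function(stack, n_slices = 10L) {
  stopifnot(inherits(stack, "voxel_stack"), n_slices >= 1)
  nz <- dim(stack$data)[3]
  starts <- seq(1L, nz, by = n_slices)
  lapply(starts, function(s) {
    e <- min(s + n_slices - 1L, nz)
    sub <- voxel_stack(stack$data[, , s:e, drop = FALSE],
                       voxel_size_um = stack$voxel_size_um,
                       channel = stack$channel)
    attr(sub, "depth_um") <- (e - s + 1L) * stack$voxel_size_um[3]
    sub
  })
}

#' Binarize a substack into a 2D vessel mask
#'
#' Maximum-intensity z-projection, Triangle auto-threshold on a 256-bin
#' histogram over the projection's range, then a radius-1 median filter to
#' remove speckle. The filter can optionally be applied before
#' thresholding instead.
#'
#' @param substack A [voxel_stack()] (or a 2D matrix already projected).
#' @param method Thresholding method for [auto_threshold()].
#' @param median_before_threshold Apply the despeckling filter to the
#'   projection instead of the mask (non-default order).
#' @param median_radius Despeckling radius in pixels.
#' @return Logical matrix vessel mask with attribute `threshold` (the
#'   0-based bin level) and `degenerate` flag.
#' @export
binarize_substack <- function(substack, method = "triangle",
                              median_before_threshold = FALSE,
                              median_radius = 1) {
  proj <- if (inherits(substack, "voxel_stack")) {
    apply(substack$data, c(1, 2), max)
  } else {
    stopifnot(is.matrix(substack))
    substack
  }
  if (median_before_threshold) proj <- median_filter(proj, median_radius)
  h <- hist_256(proj)
  lev <- auto_threshold(h, method = method)
  mask <- apply_threshold(proj, lev, lo = attr(h, "min"), hi = attr(h, "max"))
  if (!median_before_threshold) mask <- median_filter(mask, median_radius)
  attr(mask, "threshold") <- as.integer(lev)
  attr(mask, "degenerate") <- isTRUE(attr(lev, "degenerate"))
  mask
}

#' The canonical single-capillary volume
#'
#' Volume of the idealized capillary used to convert total vascular volume
#' into a capillary count: a cylinder of radius 2 um and length 75 um,
#' pi * 2^2 * 75 = 942.48 um^3.
#'
#' @param radius_um,length_um Cylinder dimensions, um.
#' @return Volume in um^3.
#' @export
capillary_volume <- function(radius_um = 2, length_um = 75) {
  stopifnot(radius_um > 0, length_um > 0)
  pi * radius_um^2 * length_um
}

#' Vascular metrics and capillary count from substack masks
#'
#' Per substack: vascular area, area fraction, volume (area fraction x
#' physical substack volume), skeleton length (skeleton pixel count x
#' pixel pitch), and width (area / length). Totals are summed over
#' substacks; mean width is the length-weighted mean; the capillary count
#' is total vascular volume divided by [capillary_volume()]. The
#' projection-based conversion is known to overestimate vascular volume
#' and underestimate vascular length for in-plane vessels; the bias is
#' reported, not corrected.
#'
#' @param masks List of logical matrices (one per substack), e.g. from
#'   [binarize_substack()].
#' @param voxel_size_um Numeric length-2 or -3 pixel size, um (x and y
#'   must be equal).
#' @param depths_um Physical depth of each substack, um.
#' @return A `census_result`: per-substack table (`area_um2`,
#'   `area_fraction`, `volume_um3`, `length_um`, `width_um`), plus totals
#'   `total_area_um2`, `fractional_volume`, `total_volume_um3`,
#'   `total_length_um`, `mean_width_um`, `capillary_count`, and a
#'   `flagged` vector naming substacks with undefined width.
#' @export
vascular_metrics <- function(masks, voxel_size_um = c(0.62, 0.62),
                             depths_um) {
  stopifnot(is.list(masks), length(masks) == length(depths_um),
            all(depths_um > 0))
  px <- voxel_size_um[1]
  if (abs(voxel_size_um[2] - px) > 1e-9) {
    stop("census metrics require square pixels")
  }
  per <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    stopifnot(is.matrix(m))
    n_px <- length(m)
    area_px <- sum(m != 0)
    skel <- skeletonize_2d(m != 0)
    len <- sum(skel) * px
    area <- area_px * px^2
    data.frame(
      substack = i,
      area_um2 = area,
      area_fraction = area_px / n_px,
      volume_um3 = area * depths_um[i],
      length_um = len,
      width_um = if (len > 0) area / len else NA_real_
    )
  })
  tab <- do.call(rbind, per)
  flagged <- tab$substack[tab$area_um2 > 0 & tab$length_um == 0]
  total_phys_vol <- sum(vapply(seq_along(masks), function(i) {
    length(masks[[i]]) * px^2 * depths_um[i]
  }, numeric(1)))
  total_volume <- sum(tab$volume_um3)
  total_length <- sum(tab$length_um)
  mean_width <- if (total_length > 0) {
    sum(tab$area_um2[tab$length_um > 0]) / total_length
  } else {
    NA_real_
  }
  structure(list(
    substacks = tab,
    total_area_um2 = sum(tab$area_um2),
    fractional_volume = total_volume / total_phys_vol,
    total_volume_um3 = total_volume,
    total_length_um = total_length,
    mean_width_um = mean_width,
    capillary_count = total_volume / capillary_volume(),
    flagged = flagged
  ), class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf(paste0(
    "capillary census: %d substacks\n",
    "  total vascular volume: %.1f um^3 (fraction %.4f)\n",
    "  total vascular length: %.1f um, mean width %.2f um\n",
    "  capillary count: %.2f (volume / %.2f um^3)\n"),
    nrow(x$substacks), x$total_volume_um3, x$fractional_volume,
    x$total_length_um, x$mean_width_um, x$capillary_count,
    capillary_volume()))
  if (length(x$flagged)) {
    cat("  flagged substacks (area without skeleton):",
        paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the full capillary census on a stack
#'
#' Convenience wrapper: [split_substacks()], [binarize_substack()] per
#' substack, then [vascular_metrics()].
#'
#' @param stack A [voxel_stack()].
#' @param n_slices Slices per substack (default 10).
#' @param method Auto-threshold method.
#' @param ... Passed to [binarize_substack()].
#' @return A `census_result`.
#' @export
capillary_census <- function(stack, n_slices = 10L, method = "triangle", ...) {
  subs <- split_substacks(stack, n_slices = n_slices)
  masks <- lapply(subs, binarize_substack, method = method, ...)
  depths <- vapply(subs, function(s) attr(s, "depth_um"), numeric(1))
  vascular_metrics(masks, voxel_size_um = stack$voxel_size_um[1:2],
                   depths_um = depths)
}
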