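# Synthetic-data generators: tubular vessel phantoms, line-scan images with
# RBC streaks, longitudinal fate tables, and two-channel coverage fixtures.
# Every generator carries its ground truth so the downstream modules can be
# validated without any raw imaging data.

#' Specify an idealized capillary as a cylinder
#'
#' The idealized capillary used throughout the package is a straight
#' cylinder; the canonical cortical capillary has radius 2 um and length
#' 75 um, giving a volume of pi * 2^2 * 75 = 942.48 um^3.
#'
#' @param p0,p1 Numeric length-3 endpoints (um).
#' @param radius Radius in um, > 0.
#' @return A `cylinder_spec` object.
#' @export
cylinder_spec <- function(p0, p1, radius = 2) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  stopifnot(length(p0) == 3, length(p1) == 3)
  if (!(radius > 0)) stop("radius must be > 0")
  if (all(p0 == p1)) stop("cylinder endpoints must differ")
  structure(list(p0 = p0, p1 = p1, radius = radius), class = "cylinder_spec")
}

#' @export
print.cylinder_spec <- function(x, ...) {
  cat(sprintf("cylinder: r = %.3g um, L = %.4g um\n", x$radius, cylinder_length(x)))
  invisible(x)
}

#' Length of a cylinder spec (um)
#' @param spec A `cylinder_spec`.
#' @export
cylinder_length <- function(spec) {
  sqrt(sum((spec$p1 - spec$p0)^2))
}

#' Analytic volume of a cylinder spec (um^3)
#' @param spec A `cylinder_spec`.
#' @export
cylinder_volume <- function(spec) {
  pi * spec$radius^2 * cylinder_length(spec)
}

#' Configuration for the vessel-phantom generator
#'
#' @param voxel_size_um Numeric length-3 voxel size (x, y, z) in um. The
#'   defaults (0.62, 0.62, 2) match a 20x two-photon stack with a 2-um
#'   z-step.
#' @param dims Integer length-3 stack shape in voxels (x, y, z).
#' @param blur_sigma_um Isotropic Gaussian blur applied after rasterization
#'   (um); 0 disables blurring.
#' @param background,vessel_intensity Intensities (arbitrary units).
#' @param shot_scale Photons per intensity unit for Poisson shot noise;
#'   0 disables shot noise.
#' @param read_noise_sd Gaussian read-noise standard deviation; 0 disables.
#' @param seed Integer RNG seed; a fixed seed makes output bit-identical.
#' @return A `synth_config` object.
#' @export
synth_config <- function(voxel_size_um = c(0.62, 0.62, 2),
                         dims = c(128L, 128L, 30L),
                         blur_sigma_um = 0.3,
                         background = 20,
                         vessel_intensity = 200,
                         shot_scale = 0,
                         read_noise_sd = 0,
                         seed = NULL) {
  stopifnot(length(voxel_size_um) == 3, all(voxel_size_um > 0),
            length(dims) == 3, all(dims >= 1),
            blur_sigma_um >= 0, shot_scale >= 0, read_noise_sd >= 0)
  structure(list(voxel_size_um = as.numeric(voxel_size_um),
                 dims = as.integer(dims),
                 blur_sigma_um = blur_sigma_um,
                 background = background,
                 vessel_intensity = vessel_intensity,
                 shot_scale = shot_scale,
                 read_noise_sd = read_noise_sd,
                 seed = seed),
            class = "synth_config")
}

# 1D Gaussian convolution along one array dimension, replicate padding.
.blur_axis <- function(a, sigma_vox, axis) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    sl <- switch(axis,
                 a[idx, , , drop = FALSE],
                 a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    out <- out + k[j] * sl
  }
  out
}

#' Generate a 3D fluorescence stack of cylindrical vessel phantoms
#'
#' Rasterizes cylinders into a voxel grid (a voxel belongs to a vessel iff
#' its center lies inside a cylinder), applies Gaussian blur and a
#' Poisson-Gaussian noise model, and returns the stack with its exact
#' analytic ground truth. The truth reflects geometry only and is
#' unaffected by blur or noise settings.
#'
#' @param specs List of [cylinder_spec()] objects (may be empty).
#' @param cfg A [synth_config()].
#' @return List with `stack` (a [voxel_stack()]) and `truth` (a
#'   `phantom_truth`: `n_vessels`, `total_length`, `total_volume`, `specs`).
#' @export
generate_vessel_stack <- function(specs, cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (inherits(specs, "cylinder_spec")) specs <- list(specs)
  lapply(specs, function(s) stopifnot(inherits(s, "cylinder_spec")))
  vs <- cfg$voxel_size_um
  dims <- cfg$dims
  extent <- dims * vs
  for (s in specs) {
    lo <- pmin(s$p0, s$p1) - s$radius
    hi <- pmax(s$p0, s$p1) + s$radius
    if (any(lo < 0) || any(hi > extent)) {
      stop(sprintf(
        "cylinder extends outside the stack bounds (stack extent %.1f x %.1f x %.1f um)",
        extent[1], extent[2], extent[3]))
    }
  }
  a <- array(FALSE, dims)
  cx <- (seq_len(dims[1]) - 0.5) * vs[1]
  cy <- (seq_len(dims[2]) - 0.5) * vs[2]
  cz <- (seq_len(dims[3]) - 0.5) * vs[3]
  for (s in specs) {
    lo <- pmin(s$p0, s$p1) - s$radius
    hi <- pmax(s$p0, s$p1) + s$radius
    ix <- which(cx >= lo[1] & cx <= hi[1])
    iy <- which(cy >= lo[2] & cy <= hi[2])
    iz <- which(cz >= lo[3] & cz <= hi[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    g <- expand.grid(x = cx[ix], y = cy[iy], z = cz[iz])
    d <- s$p1 - s$p0
    L2 <- sum(d^2)
    px <- g$x - s$p0[1]; py <- g$y - s$p0[2]; pz <- g$z - s$p0[3]
    t <- pmin(pmax((px * d[1] + py * d[2] + pz * d[3]) / L2, 0), 1)
    dx <- px - t * d[1]; dy <- py - t * d[2]; dz <- pz - t * d[3]
    inside <- (dx^2 + dy^2 + dz^2) <= s$radius^2 & t > 0 & t < 1
    sub <- array(a[ix, iy, iz], c(length(ix), length(iy), length(iz)))
    sub[inside] <- TRUE
    a[ix, iy, iz] <- sub
  }
  img <- array(cfg$background, dims)
  img[a] <- cfg$vessel_intensity
  if (cfg$blur_sigma_um > 0) {
    for (ax in 1:3) img <- .blur_axis(img, cfg$blur_sigma_um / vs[ax], ax)
  }
  img <- with_seed(cfg$seed, {
    if (cfg$shot_scale > 0) {
      img <- stats::rpois(length(img), lambda = pmax(img, 0) * cfg$shot_scale) /
        cfg$shot_scale
      dim(img) <- dims
    }
    if (cfg$read_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = cfg$read_noise_sd)
      dim(img) <- dims
    }
    img
  })
  truth <- structure(list(
    n_vessels = length(specs),
    total_length = sum(vapply(specs, cylinder_length, numeric(1))),
    total_volume = sum(vapply(specs, cylinder_volume, numeric(1))),
    specs = specs
  ), class = "phantom_truth")
  list(stack = voxel_stack(img, voxel_size_um = vs, channel = "plasma"),
       truth = truth)
}

#' Generate a line-scan image with diagonal RBC streaks
#'
#' Emulates repeated 1D scanning along a capillary axis: moving red blood
#' cells exclude the plasma dye and appear as dark diagonal streaks whose
#' displacement per line equals `velocity * line_period`. A velocity of 0
#' yields vertical (time-axis-parallel) streaks.
#'
#' @param velocity RBC velocity in um/s (>= 0; sign of travel set by
#'   `direction`).
#' @param line_period_ms Time per scanned line (ms).
#' @param pixel_pitch_um Spatial calibration (um/pixel).
#' @param n_lines,n_pixels Image size (lines = time axis rows).
#' @param streak_density Streaks per pixel of scan width (default 0.05, i.e.
#'   one streak every 20 pixels).
#' @param direction +1 or -1: sign of streak drift along the spatial axis.
#' @param background,streak_depth Plasma intensity and streak darkening.
#' @param streak_width_um Apparent RBC width (FWHM of the dark dip), um.
#' @param noise_sd Additive Gaussian noise.
#' @param seed Integer RNG seed.
#' @return A `linescan_image`: list with `img` (lines x pixels matrix),
#'   `line_period_ms`, `pixel_pitch_um`.
#' @export
generate_linescan <- function(velocity, line_period_ms = 1, pixel_pitch_um = 2,
                              n_lines = 256L, n_pixels = 64L,
                              streak_density = 0.05, direction = 1,
                              background = 150, streak_depth = 120,
                              streak_width_um = 4, noise_sd = 0, seed = NULL) {
  stopifnot(velocity >= 0, line_period_ms > 0, pixel_pitch_um > 0,
            n_lines >= 2, n_pixels >= 2, direction %in% c(-1, 1))
  dpx <- direction * velocity * (line_period_ms / 1000) / pixel_pitch_um
  if (abs(dpx) > n_pixels) {
    stop("streak displacement per line exceeds the scan width (aliasing)")
  }
  span <- abs(dpx) * (n_lines - 1)
  x_lo <- min(1, 1 - if (dpx > 0) span else 0) - 2
  x_hi <- max(n_pixels, n_pixels + if (dpx < 0) span else 0) + 2
  spacing <- 1 / streak_density
  intercepts <- with_seed(seed, {
    base <- seq(x_lo, x_hi, by = spacing)
    base + stats::runif(length(base), -0.2, 0.2) * spacing
  })
  sig_px <- streak_width_um / pixel_pitch_um / (2 * sqrt(2 * log(2)))
  img <- matrix(background, n_lines, n_pixels)
  px <- seq_len(n_pixels)
  for (j in seq_len(n_lines)) {
    centers <- intercepts + dpx * (j - 1)
    centers <- centers[centers > -3 * sig_px & centers < n_pixels + 3 * sig_px]
    if (length(centers)) {
      dip <- rowSums(exp(-outer(px, centers, "-")^2 / (2 * sig_px^2)))
      img[j, ] <- background - streak_depth * pmin(dip, 1)
    }
  }
  if (noise_sd > 0) {
    img <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
      img + matrix(stats::rnorm(length(img), sd = noise_sd), n_lines, n_pixels)
    })
  }
  linescan_image(img, line_period_ms = line_period_ms,
                 pixel_pitch_um = pixel_pitch_um)
}

# Front-loaded default recanalization hazards: conditional probability of
# clearing per imaging interval, chosen so that ~75-80% of obstructions
# recanalize within 24 hr (the last interval is forced to 1 for tracks
# destined to recanalize so every track has a terminal fate at the horizon).
.default_hazards <- function(n_intervals) {
  h <- c(0.60, 0.65, 0.80, 0.60, rep(0.5, max(0, n_intervals - 4)))
  h <- h[seq_len(n_intervals)]
  h[n_intervals] <- 1
  h
}

#' Generate a longitudinal capillary fate table
#'
#' Draws one row per track and imaging timepoint. Each track receives a
#' terminal fate (pruned, recanalized-by-washout, or
#' recanalized-by-angiophagy) and a status trajectory consistent with it:
#' obstructed at day 0, then either cleared at a hazard-sampled time or
#' pruned. A fraction of pruned tracks transiently regain flow before
#' elimination, as observed in longitudinal imaging. Defaults emulate the
#' 21-day microsphere cohort (162 obstructions across 14 mice, 30% pruning,
#' 2% angiophagy).
#'
#' @param n_tracks Number of obstructed capillaries.
#' @param p_prune,p_angiophagy Terminal fate probabilities (washout takes
#'   the remainder); `p_prune + p_angiophagy <= 1`.
#' @param timepoints Imaging days, starting at 0.
#' @param recanalization_hazards Conditional clearing probability per
#'   interval (`length(timepoints) - 1` values); `NULL` uses a front-loaded
#'   default.
#' @param seed Integer RNG seed.
#' @param quota Optional named integer vector
#'   `c(pruned =, washout =, angiophagy =)` summing to `n_tracks`:
#'   deterministic composition mode reproducing an exact fate breakdown
#'   (e.g. 49/110/3).
#' @param n_animals Tracks are assigned round-robin to this many animals.
#' @param p_transient Fraction of pruned tracks that transiently recanalize
#'   before elimination.
#' @return Data frame with one row per track-timepoint: `track`, `animal`,
#'   `obstruction_type`, `branch_order`, `depth_um`, `n_microspheres`,
#'   `branch_separation`, `time_day`, `status`
#'   (`flowing|obstructed|pruned`), `route` (`washout|angiophagy|none`).
#' @export
generate_fate_table <- function(n_tracks = 162L, p_prune = 0.30,
                                p_angiophagy = 3 / 162,
                                timepoints = c(0, 0.25, 0.5, 1, 2, 4, 10, 15, 21),
                                recanalization_hazards = NULL,
                                seed = NULL, quota = NULL,
                                n_animals = 14L, p_transient = 0.25) {
  if (length(timepoints) == 0) stop("timepoint list must not be empty")
  timepoints <- sort(unique(as.numeric(timepoints)))
  if (timepoints[1] != 0) stop("timepoints must start at day 0")
  if (length(timepoints) < 2) stop("need at least one post-obstruction timepoint")
  stopifnot(p_prune >= 0, p_prune <= 1, p_angiophagy >= 0, p_angiophagy <= 1)
  if (p_prune + p_angiophagy > 1) stop("p_prune + p_angiophagy must be <= 1")
  n_int <- length(timepoints) - 1L
  if (is.null(recanalization_hazards)) {
    recanalization_hazards <- .default_hazards(n_int)
  }
  stopifnot(length(recanalization_hazards) == n_int,
            all(recanalization_hazards >= 0), all(recanalization_hazards <= 1))
  with_seed(seed, {
    if (!is.null(quota)) {
      stopifnot(all(c("pruned", "washout", "angiophagy") %in% names(quota)),
                sum(quota) == n_tracks)
      fates <- rep(c("pruned", "washout", "angiophagy"),
                   times = quota[c("pruned", "washout", "angiophagy")])
    } else {
      fates <- sample(c("pruned", "washout", "angiophagy"), n_tracks,
                      replace = TRUE,
                      prob = c(p_prune, 1 - p_prune - p_angiophagy, p_angiophagy))
    }
    g <- default_branch_order_table()
    orders <- sample(g$order, n_tracks, replace = TRUE, prob = g$g)
    depth <- stats::runif(n_tracks, 50, 350)
    animal <- rep_len(seq_len(n_animals), n_tracks)
    sep <- sample(2:5, n_tracks, replace = TRUE)
    haz <- recanalization_hazards
    sample_recan_idx <- function() {
      for (k in seq_len(n_int)) {
        if (stats::runif(1) < haz[k]) return(k + 1L)
      }
      n_int + 1L
    }
    rows <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      status <- rep("obstructed", length(timepoints))
      route <- "none"
      f <- fates[i]
      if (f %in% c("washout", "angiophagy")) {
        k <- sample_recan_idx()
        status[seq_along(timepoints) >= k] <- "flowing"
        route <- f
      } else {
        # pruning unfolds over days; restrict elimination to day >= 2
        prune_ok <- which(timepoints >= 2)
        if (!length(prune_ok)) prune_ok <- length(timepoints)
        transient <- stats::runif(1) < p_transient && length(timepoints) >= 3
        if (transient) {
          k <- min(sample_recan_idx(), length(timepoints) - 1L)
          cand <- prune_ok[prune_ok > k]
          if (!length(cand)) cand <- length(timepoints)
          kp <- cand[sample.int(length(cand), 1)]
          status[seq_along(timepoints) >= k] <- "flowing"
          route <- "washout"
        } else {
          kp <- prune_ok[sample.int(length(prune_ok), 1)]
        }
        status[seq_along(timepoints) >= kp] <- "pruned"
      }
      rows[[i]] <- data.frame(
        track = i, animal = animal[i], obstruction_type = "microsphere",
        branch_order = orders[i], depth_um = depth[i], n_microspheres = 1L,
        branch_separation = sep[i], time_day = timepoints, status = status,
        route = route, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate a two-channel projection with an exact coverage quota
#'
#' Builds a vessel mask (a horizontal band) and places signal on exactly
#' `round(signal_coverage / 100 * n_mask_pixels)` vessel pixels, so the
#' ground-truth coverage is a pixel-count quota. Intensity channels carry
#' the masks at fixed intensities on a dark background.
#'
#' @param vessel_mask_fraction Fraction of image pixels covered by the
#'   vessel band.
#' @param signal_coverage Requested coverage in percent (0-100).
#' @param seed RNG seed (used by the `"random"` arrangement).
#' @param dims Image size (rows, cols).
#' @param arrangement `"random"` scatters signal pixels over the mask;
#'   `"block"` places them as a contiguous block (robust to median
#'   filtering in full-pipeline round trips).
#' @param background,vessel_intensity,signal_intensity Channel intensities.
#' @return List with logical `vessel_mask` and `signal_mask`, numeric
#'   `vessel_channel` and `signal_channel`, and `coverage_true` (%).
#' @export
generate_coloc_projection <- function(vessel_mask_fraction = 0.2,
                                      signal_coverage = 20, seed = NULL,
                                      dims = c(128L, 128L),
                                      arrangement = c("random", "block"),
                                      background = 10, vessel_intensity = 180,
                                      signal_intensity = 150) {
  arrangement <- match.arg(arrangement)
  if (signal_coverage < 0 || signal_coverage > 100) {
    stop("signal_coverage must be in [0, 100]")
  }
  stopifnot(vessel_mask_fraction > 0, vessel_mask_fraction <= 1)
  nr <- dims[1]; nc <- dims[2]
  band <- max(1L, round(vessel_mask_fraction * nr))
  r0 <- floor((nr - band) / 2) + 1L
  vessel <- matrix(FALSE, nr, nc)
  vessel[r0:(r0 + band - 1L), ] <- TRUE
  mask_idx <- which(vessel)
  n_sig <- round(signal_coverage / 100 * length(mask_idx))
  signal <- matrix(FALSE, nr, nc)
  if (n_sig > 0) {
    pick <- if (arrangement == "random") {
      with_seed(seed, sample(mask_idx, n_sig))
    } else {
      # column-major order keeps the block contiguous inside the band
      mask_idx[seq_len(n_sig)]
    }
    signal[pick] <- TRUE
  }
  vch <- matrix(background, nr, nc); vch[vessel] <- vessel_intensity
  sch <- matrix(background, nr, nc); sch[signal] <- signal_intensity
  list(vessel_mask = vessel, signal_mask = signal,
       vessel_channel = vch, signal_channel = sch,
       coverage_true = 100 * n_sig / length(mask_idx))
}
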