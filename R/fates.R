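# Longitudinal accounting of obstructed capillaries: eligibility filters,
# fate classification at a horizon, recanalization curves, obstruction-rate
# estimation, branch-order risk partitioning, and normalized microsphere
# densities.

.track_cols <- c("track", "branch_order", "n_microspheres",
                 "branch_separation", "time_day", "status", "route")

.check_tracks <- function(tracks, cols = .track_cols) {
  missing <- setdiff(cols, names(tracks))
  if (length(missing)) {
    stop("track table is missing fields: ", paste(missing, collapse = ", "))
  }
  invisible(tracks)
}

#' Filter obstructed-capillary tracks for eligibility
#'
#' Retains tracks with at most one lodged microsphere and at least two
#' branching points separating them from the nearest other obstruction;
#' all other tracks are excluded from fate accounting.
#'
#' @param tracks Long-format track table (see [generate_fate_table()]).
#' @return The eligible subset, same format.
#' @export
filter_eligible <- function(tracks) {
  .check_tracks(tracks, c("track", "n_microspheres", "branch_separation"))
  if (anyNA(tracks$n_microspheres) || anyNA(tracks$branch_separation)) {
    stop("n_microspheres / branch_separation must be populated for all tracks")
  }
  keep <- tracks$n_microspheres <= 1 & tracks$branch_separation >= 2
  tracks[keep, , drop = FALSE]
}

# Terminal state of each track at the horizon: status at the latest
# timepoint <= horizon.
.terminal_states <- function(tracks, horizon) {
  .check_tracks(tracks, c("track", "time_day", "status", "route"))
  eligible <- tracks[tracks$time_day <= horizon, , drop = FALSE]
  if (!nrow(eligible)) stop("no observations at or before the horizon")
  by_track <- split(eligible, eligible$track)
  do.call(rbind, lapply(by_track, function(tt) {
    tt <- tt[order(tt$time_day), , drop = FALSE]
    tt[nrow(tt), c("track", "status", "route"), drop = FALSE]
  }))
}

#' Summarize capillary fates at a horizon
#'
#' Classifies each track by its terminal state: pruned, or intact and
#' flowing via washout or angiophagy. Percentages are over pooled tracks.
#'
#' @param tracks Long-format track table.
#' @param horizon_day Day at which fates are read (default 21).
#' @return A `fate_summary`: `n_total`, `n_pruned`, `n_washout`,
#'   `n_angiophagy`, `pct_pruned`, `pct_intact`, `pct_angiophagy`.
#' @export
summarize_fates <- function(tracks, horizon_day = 21) {
  term <- .terminal_states(tracks, horizon_day)
  if (any(term$status == "obstructed")) {
    stop("unknown terminal status: some tracks are still obstructed at the ",
         "horizon; extend the horizon or resolve their fates")
  }
  bad <- !term$status %in% c("flowing", "pruned")
  if (any(bad)) {
    stop("unknown terminal status: ", paste(unique(term$status[bad]),
                                            collapse = ", "))
  }
  n_total <- nrow(term)
  n_pruned <- sum(term$status == "pruned")
  intact <- term[term$status == "flowing", , drop = FALSE]
  if (any(!intact$route %in% c("washout", "angiophagy"))) {
    stop("intact tracks must have a recanalization route (washout/angiophagy)")
  }
  n_washout <- sum(intact$route == "washout")
  n_angiophagy <- sum(intact$route == "angiophagy")
  structure(list(
    n_total = n_total, n_pruned = n_pruned, n_washout = n_washout,
    n_angiophagy = n_angiophagy,
    pct_pruned = 100 * n_pruned / n_total,
    pct_intact = 100 * (n_washout + n_angiophagy) / n_total,
    pct_angiophagy = 100 * n_angiophagy / n_total
  ), class = "fate_summary")
}

#' @export
print.fate_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "capillary fates (n = %d obstructions)\n",
    "  pruned:              %3d (%.1f%%)\n",
    "  intact via washout:  %3d\n",
    "  intact via angiophagy: %d (%.1f%%)\n",
    "  intact total:        %.1f%%\n"),
    x$n_total, x$n_pruned, x$pct_pruned, x$n_washout, x$n_angiophagy,
    x$pct_angiophagy, x$pct_intact))
  invisible(x)
}

#' Recanalization curve: percent of obstructions remaining over time
#'
#' Computes, for each animal, the percent of its time-0 obstructions whose
#' status is still `obstructed` at each timepoint, then averages across
#' animals (per-animal normalization before group averaging). The curve
#' starts at 100% by construction.
#'
#' @param tracks Long-format track table with an `animal` column.
#' @param timepoints Timepoints (days) to evaluate; defaults to all
#'   timepoints present.
#' @return Data frame with `time_day`, `pct_remaining` (group mean), and
#'   `n_animals`.
#' @export
recanalization_curve <- function(tracks, timepoints = NULL) {
  .check_tracks(tracks, c("track", "animal", "time_day", "status"))
  if (is.null(timepoints)) timepoints <- sort(unique(tracks$time_day))
  timepoints <- sort(timepoints)
  per_animal <- lapply(split(tracks, tracks$animal), function(tt) {
    t0 <- tt[tt$time_day == timepoints[1], , drop = FALSE]
    n0 <- sum(t0$status == "obstructed")
    if (n0 == 0) return(NULL)
    vapply(timepoints, function(tp) {
      obs <- tt[tt$time_day == tp, , drop = FALSE]
      100 * sum(obs$status == "obstructed") / n0
    }, numeric(1))
  })
  dropped <- vapply(per_animal, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " animal(s) with zero time-0 obstructions excluded")
  }
  per_animal <- per_animal[!dropped]
  if (!length(per_animal)) stop("no animals with time-0 obstructions")
  mat <- do.call(rbind, per_animal)
  data.frame(time_day = timepoints,
             pct_remaining = colMeans(mat),
             n_animals = nrow(mat))
}

#' Spontaneous obstruction rate from a capillary survey
#'
#' Scales the fraction of capillaries found obstructed during an
#' observation window to a daily rate:
#' `rate = (n_obstructed / n_sampled) * (24 / window_hr) * 100` percent of
#' capillaries per day.
#'
#' @param n_obstructed Obstructed capillaries observed.
#' @param n_sampled Capillaries sampled.
#' @param window_hr Observation window, hours.
#' @return An `obstruction_rate`: `rate_pct_per_day`, `window_hr`,
#'   `n_obstructed`, `basis` (here `n_sampled`), and `odds` (1 in N per
#'   window).
#' @export
spontaneous_rate_survey <- function(n_obstructed, n_sampled, window_hr) {
  stopifnot(n_obstructed >= 0, window_hr > 0)
  if (n_sampled <= 0) stop("n_sampled must be positive")
  rate <- (n_obstructed / n_sampled) * (24 / window_hr) * 100
  structure(list(rate_pct_per_day = rate, window_hr = window_hr,
                 n_obstructed = n_obstructed, basis = n_sampled,
                 odds = if (n_obstructed > 0) n_sampled / n_obstructed
                        else Inf),
            class = "obstruction_rate")
}

#' Spontaneous obstruction rate from post-mortem densities
#'
#' Converts an obstruction density (per mm^3 of cortex, accumulated over
#' `window_hr`) into a daily rate against the capillary density:
#' `rate = (obstructions_per_mm3 / capillaries_per_mm3) * (24 / window_hr)
#' * 100`. The unrounded value is returned.
#'
#' @param obstructions_per_mm3 Labeled obstructions per mm^3.
#' @param window_hr Accumulation window, hours.
#' @param capillaries_per_mm3 Capillary density (default 20,000 per mm^3).
#' @return An `obstruction_rate`.
#' @export
spontaneous_rate_density <- function(obstructions_per_mm3, window_hr,
                                     capillaries_per_mm3 = 20000) {
  stopifnot(obstructions_per_mm3 >= 0, window_hr > 0)
  if (capillaries_per_mm3 <= 0) stop("capillary density must be positive")
  rate <- (obstructions_per_mm3 / capillaries_per_mm3) * (24 / window_hr) * 100
  structure(list(rate_pct_per_day = rate, window_hr = window_hr,
                 n_obstructed = obstructions_per_mm3,
                 basis = capillaries_per_mm3,
                 odds = if (obstructions_per_mm3 > 0)
                   capillaries_per_mm3 / obstructions_per_mm3 else Inf),
            class = "obstruction_rate")
}

#' @export
print.obstruction_rate <- function(x, ...) {
  cat(sprintf("obstruction rate: %.4g%% of capillaries per day (%g-hr window)\n",
              x$rate_pct_per_day, x$window_hr))
  invisible(x)
}

#' Partition an overall obstruction rate into per-branch-order risks
#'
#' Branch orders count branching points from the penetrating arteriole
#' (order 0); obstructions concentrate at low orders. Given the fraction
#' of all capillaries at each order (`f`), the fraction of obstructions at
#' each order (`g`), and the overall daily obstruction rate `R`, the
#' per-order daily risk is `r_o = R * g_o / f_o`, so that the
#' population-weighted risk recovers the overall rate:
#' `sum(f_o * r_o) = R`.
#'
#' @param f Per-order capillary fractions (sum to 1).
#' @param g Per-order obstruction fractions (sum to 1).
#' @param R Overall daily obstruction rate (fraction of capillaries/day).
#' @param order Branch-order labels (default `seq_along(f)`).
#' @return A `branch_order_table` data frame with columns `order`, `f`,
#'   `g`, `r` and attribute `R`.
#' @export
branch_order_risks <- function(f, g, R, order = seq_along(f)) {
  stopifnot(length(f) == length(g), length(order) == length(f),
            all(f >= 0), all(g >= 0), R >= 0)
  if (abs(sum(f) - 1) > 1e-6 || abs(sum(g) - 1) > 1e-6) {
    stop("f and g must each sum to 1")
  }
  if (any(g > 0 & f == 0)) {
    stop("obstructions (g > 0) at a branch order with no capillaries (f = 0)")
  }
  r <- ifelse(f > 0, R * g / f, 0)
  tab <- data.frame(order = order, f = f, g = g, r = r)
  attr(tab, "R") <- R
  class(tab) <- c("branch_order_table", "data.frame")
  tab
}

#' Whole-cortex capillary pool
#'
#' Extrapolates a capillary density to a total count for the cortex:
#' with ~180 mm^3 of cortex at ~20,000 capillaries per mm^3, about
#' 3.6 million capillaries.
#'
#' @param cortex_volume_mm3 Cortical volume, mm^3.
#' @param capillaries_per_mm3 Capillary density, per mm^3.
#' @return Total capillary count.
#' @export
total_capillary_pool <- function(cortex_volume_mm3 = 180,
                                 capillaries_per_mm3 = 20000) {
  stopifnot(cortex_volume_mm3 > 0, capillaries_per_mm3 > 0)
  cortex_volume_mm3 * capillaries_per_mm3
}

#' Normalize experimental densities to cohort controls
#'
#' Each experimental density is divided by the mean density of its
#' cohort's control animals; normalized ratios are then averaged across
#' cohorts.
#'
#' @param experimental Experimental densities.
#' @param experimental_cohort Cohort label per experimental animal.
#' @param control Control densities.
#' @param control_cohort Cohort label per control animal.
#' @return List with `ratios` (data frame: `cohort`, `ratio`),
#'   `cohort_means`, and `grand_mean` (mean of cohort means).
#' @export
normalized_density <- function(experimental, experimental_cohort = 1,
                               control, control_cohort = 1) {
  experimental_cohort <- rep_len(experimental_cohort, length(experimental))
  control_cohort <- rep_len(control_cohort, length(control))
  ctrl_means <- tapply(control, control_cohort, mean)
  missing <- setdiff(unique(experimental_cohort), names(ctrl_means))
  if (length(missing)) {
    stop("cohort(s) without control animals: ", paste(missing, collapse = ", "))
  }
  ratio <- experimental / as.numeric(ctrl_means[as.character(experimental_cohort)])
  cohort_means <- tapply(ratio, experimental_cohort, mean)
  list(ratios = data.frame(cohort = experimental_cohort, ratio = ratio),
       cohort_means = as.numeric(cohort_means),
       grand_mean = mean(cohort_means))
}
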