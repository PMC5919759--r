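# Branch-order-structured capillary rarefaction model: repeated 2-hr cycles
# of obstruction and pruning applied to a theoretical population of
# capillaries, predicting density loss over months.

#' Packaged default branch-order distribution (estimate)
#'
#' An ESTIMATE of the branch-order structure of the cortical capillary bed
#' and of obstruction risk, reconstructed from figure-level descriptions:
#' the all-capillary distribution is broad (support at orders 1-8, mean
#' near order 4-5) while obstructions concentrate at low orders with a
#' peak at order 3. The exact measured distribution is not reproduced in
#' text, so headline runs should supply their own table where available;
#' this default exists so the model is runnable out of the box.
#'
#' @param R Overall daily obstruction rate used to derive per-order risks
#'   (default 0.00118/day).
#' @return A `branch_order_table` (see [branch_order_risks()]).
#' @export
default_branch_order_table <- function(R = 0.00118) {
  f <- c(0.06, 0.10, 0.15, 0.18, 0.18, 0.14, 0.11, 0.08)
  g <- c(0.17, 0.25, 0.28, 0.15, 0.08, 0.04, 0.02, 0.01)
  branch_order_risks(f = f, g = g, R = R, order = 1:8)
}

#' Read a branch-order table from CSV
#'
#' Expects columns `order`, `f` and either `g` (obstruction fractions,
#' converted to risks via [branch_order_risks()]) or `r` (per-order daily
#' risks used as-is).
#'
#' @param path CSV file path.
#' @param R Overall daily rate (required when the file carries `g`).
#' @return A `branch_order_table`.
#' @export
read_branch_order_table <- function(path, R = 0.00118) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("order", "f") %in% names(tab)))
  if ("g" %in% names(tab)) {
    branch_order_risks(tab$f, tab$g, R = R, order = tab$order)
  } else if ("r" %in% names(tab)) {
    out <- data.frame(order = tab$order, f = tab$f,
                      g = tab$f * tab$r / sum(tab$f * tab$r), r = tab$r)
    attr(out, "R") <- sum(tab$f * tab$r)
    class(out) <- c("branch_order_table", "data.frame")
    out
  } else {
    stop("branch-order CSV needs a 'g' or 'r' column")
  }
}

#' Configuration for the rarefaction model
#'
#' @param n_capillaries Size of the theoretical capillary population
#'   (default 100,000).
#' @param cycle_hr Update cycle, hours (default 2; must divide 24).
#' @param daily_rate Overall obstruction rate, fraction of capillaries per
#'   day (default 0.00118).
#' @param p_prune Probability that an obstructed capillary is pruned
#'   (default 0.30).
#' @param duration_days Simulated duration, days.
#' @param branch_table Optional [branch_order_risks()] table; `NULL` runs
#'   the homogeneous model (every capillary carries `daily_rate`).
#' @param seed RNG seed for the Monte-Carlo mode.
#' @return A `rarefaction_config` object.
#' @export
rarefaction_config <- function(n_capillaries = 100000L, cycle_hr = 2,
                               daily_rate = 0.00118, p_prune = 0.30,
                               duration_days = 365, branch_table = NULL,
                               seed = NULL) {
  stopifnot(n_capillaries >= 1, cycle_hr > 0, daily_rate >= 0,
            p_prune >= 0, p_prune <= 1, duration_days > 0)
  if (abs(24 / cycle_hr - round(24 / cycle_hr)) > 1e-9) {
    stop("cycle_hr must divide a day into an integer number of windows")
  }
  if (!is.null(branch_table)) {
    stopifnot(inherits(branch_table, "branch_order_table"))
    if (abs(attr(branch_table, "R") - daily_rate) > 1e-12) {
      branch_table <- branch_order_risks(branch_table$f, branch_table$g,
                                         R = daily_rate,
                                         order = branch_table$order)
    }
  }
  structure(list(n_capillaries = as.integer(n_capillaries),
                 cycle_hr = cycle_hr, daily_rate = daily_rate,
                 p_prune = p_prune, duration_days = duration_days,
                 branch_table = branch_table, seed = seed),
            class = "rarefaction_config")
}

# Per-order per-cycle risks and initial counts for a config.
.rarefaction_setup <- function(cfg) {
  if (is.null(cfg$branch_table)) {
    f <- 1
    r_day <- cfg$daily_rate
    orders <- 0L
  } else {
    f <- cfg$branch_table$f
    r_day <- cfg$branch_table$r
    orders <- cfg$branch_table$order
  }
  r_cycle <- r_day * cfg$cycle_hr / 24
  if (any(r_cycle >= 1)) stop("per-cycle obstruction risk >= 1; shorten the cycle")
  n_cycles <- round(cfg$duration_days * 24 / cfg$cycle_hr)
  list(f = f, r_cycle = r_cycle, orders = orders, n_cycles = n_cycles)
}

.trajectory <- function(days, remaining, per_order, orders, mode) {
  out <- data.frame(day = days, remaining = remaining)
  attr(out, "per_order") <- per_order
  attr(out, "orders") <- orders
  attr(out, "mode") <- mode
  class(out) <- c("rarefaction_trajectory", "data.frame")
  out
}

#' Expected-value rarefaction trajectory
#'
#' Deterministic form of the model: every `cycle_hr` window, each branch
#' order loses `N_o * r_o,cycle * p_prune` capillaries, where the
#' per-cycle risk is the daily risk scaled linearly
#' (`r_o,cycle = r_o * cycle_hr / 24`). Obstructions that are not pruned
#' revert to flowing within the cycle, and branch-order membership is
#' fixed for the run. The remaining fraction at each timepoint is the
#' summed population over its initial size.
#'
#' @param cfg A [rarefaction_config()].
#' @return A `rarefaction_trajectory` data frame (`day`, `remaining`) with
#'   the per-order population matrix in attribute `per_order`.
#' @export
simulate_expected <- function(cfg) {
  stopifnot(inherits(cfg, "rarefaction_config"))
  s <- .rarefaction_setup(cfg)
  N <- cfg$n_capillaries * s$f
  N0 <- sum(N)
  loss_factor <- 1 - s$r_cycle * cfg$p_prune
  per_order <- matrix(0, nrow = s$n_cycles + 1, ncol = length(N))
  per_order[1, ] <- N
  for (k in seq_len(s$n_cycles)) {
    N <- N * loss_factor
    per_order[k + 1, ] <- N
  }
  days <- (0:s$n_cycles) * cfg$cycle_hr / 24
  .trajectory(days, rowSums(per_order) / N0, per_order, s$orders, "expected")
}

#' Monte-Carlo rarefaction trajectory
#'
#' Stochastic realization of the same update: per cycle and branch order,
#' the number of obstructed capillaries is Binomial(N_o, r_o,cycle) and
#' the number pruned is Binomial(obstructed, p_prune); pruned capillaries
#' are removed. Reproducible under a fixed seed.
#'
#' @param cfg A [rarefaction_config()]; set `cfg$seed` for
#'   reproducibility.
#' @return A `rarefaction_trajectory` data frame.
#' @export
simulate_monte_carlo <- function(cfg) {
  stopifnot(inherits(cfg, "rarefaction_config"))
  s <- .rarefaction_setup(cfg)
  N <- round(cfg$n_capillaries * s$f)
  N0 <- sum(N)
  k_orders <- length(N)
  per_order <- matrix(0, nrow = s$n_cycles + 1, ncol = k_orders)
  per_order[1, ] <- N
  with_seed(cfg$seed, {
    for (k in seq_len(s$n_cycles)) {
      obstructed <- stats::rbinom(k_orders, N, s$r_cycle)
      pruned <- stats::rbinom(k_orders, obstructed, cfg$p_prune)
      N <- N - pruned
      per_order[k + 1, ] <- N
    }
  })
  days <- (0:s$n_cycles) * cfg$cycle_hr / 24
  .trajectory(days, rowSums(per_order) / N0, per_order, s$orders,
              "montecarlo")
}

#' @export
print.rarefaction_trajectory <- function(x, ...) {
  cat(sprintf(
    "rarefaction trajectory (%s): %.4g days, remaining %.2f%% at end\n",
    attr(x, "mode"), max(x$day), 100 * x$remaining[nrow(x)]))
  invisible(x)
}

#' Expected remaining fraction at a given day
#'
#' Interpolates the expected-value trajectory at the requested day.
#'
#' @param cfg A [rarefaction_config()] (its `duration_days` must cover
#'   `at_day`).
#' @param at_day Day at which to evaluate (0 <= at_day <= duration).
#' @return Remaining fraction of the initial capillary population.
#' @export
predicted_remaining <- function(cfg, at_day) {
  stopifnot(inherits(cfg, "rarefaction_config"))
  if (at_day < 0 || at_day > cfg$duration_days) {
    stop("at_day outside the simulated range")
  }
  traj <- simulate_expected(cfg)
  stats::approx(traj$day, traj$remaining, xout = at_day)$y
}
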