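# Obstruction-fate accounting, recanalization curves, rates, branch-order
# risks, and normalized densities.

test_that("eligibility filter excludes multi-microsphere and crowded tracks", {
  tr <- data.frame(track = 1:4, n_microspheres = c(1, 2, 1, 0),
                   branch_separation = c(3, 3, 1, 2))
  kept <- filter_eligible(tr)
  expect_equal(kept$track, c(1, 4))
  ok <- data.frame(track = 1:10, n_microspheres = 1, branch_separation = 2)
  expect_equal(nrow(filter_eligible(ok)), 10)
  bad <- data.frame(track = 1, n_microspheres = NA, branch_separation = 2)
  expect_error(filter_eligible(bad), "populated")
})

test_that("the 162-track worked example reproduces the published composition", {
  ft <- generate_fate_table(quota = c(pruned = 49, washout = 110,
                                      angiophagy = 3), seed = 1)
  s <- summarize_fates(ft, 21)
  expect_equal(s$n_total, 162)
  expect_equal(round(s$pct_pruned, 1), 30.2)
  expect_equal(round(s$pct_intact, 1), 69.8)
  expect_equal(round(s$pct_angiophagy, 2), 1.85)
  expect_equal(round(s$pct_angiophagy), 2)
  expect_equal(s$pct_pruned + s$pct_intact, 100)
})

test_that("fate percentages are order-invariant and handle degenerate mixes", {
  ft <- generate_fate_table(n_tracks = 50, seed = 2)
  s1 <- summarize_fates(ft, 21)
  perm <- ft[sample(nrow(ft)), ]
  s2 <- summarize_fates(perm, 21)
  expect_equal(s1$pct_pruned, s2$pct_pruned)
  all_rec <- generate_fate_table(n_tracks = 30, p_prune = 0,
                                 p_angiophagy = 0, seed = 3)
  expect_equal(summarize_fates(all_rec, 21)$pct_pruned, 0)
})

test_that("tracks still obstructed at the horizon raise an error", {
  tr <- data.frame(track = 1, animal = 1, time_day = c(0, 21),
                   status = c("obstructed", "obstructed"), route = "none")
  expect_error(summarize_fates(tr, 21), "unknown terminal status")
})

test_that("recanalization curves start at 100% and match direct counts", {
  # one animal, 36 obstructions, 27 recanalized by 24 hr
  status_at <- function(i, t) {
    if (t == 0) "obstructed" else if (i <= 27) "flowing" else "obstructed"
  }
  tr <- do.call(rbind, lapply(1:36, function(i) {
    data.frame(track = i, animal = 1, time_day = c(0, 1),
               status = c(status_at(i, 0), status_at(i, 1)), route = "none")
  }))
  curve <- recanalization_curve(tr)
  expect_equal(curve$pct_remaining[curve$time_day == 0], 100)
  expect_equal(curve$pct_remaining[curve$time_day == 1], 25)
  # 75% recanalized: inside the reported 75-80% band
  expect_gte(100 - curve$pct_remaining[curve$time_day == 1], 75)
  expect_lte(100 - curve$pct_remaining[curve$time_day == 1], 80)
})

test_that("generated curves are monotone non-increasing and per-animal averaged", {
  for (seed in 1:4) {
    ft <- generate_fate_table(seed = seed)
    curve <- recanalization_curve(ft)
    expect_equal(curve$pct_remaining[1], 100)
    expect_true(all(diff(curve$pct_remaining) <= 1e-9))
  }
  # an animal with no time-0 obstructions is excluded with a warning
  ft <- generate_fate_table(n_tracks = 10, n_animals = 2, seed = 5)
  ft$status[ft$animal == 2 & ft$time_day == 0] <- "flowing"
  expect_warning(recanalization_curve(ft), "excluded")
})

test_that("survey obstruction rate scales a window count to percent per day", {
  r <- spontaneous_rate_survey(2, 20334, 2)
  expect_equal(round(r$rate_pct_per_day, 3), 0.118)
  expect_equal(spontaneous_rate_survey(0, 5000, 2)$rate_pct_per_day, 0)
  # expressed as odds: about 1 in 10,000 capillaries per window
  expect_equal(r$odds, 20334 / 2)
  expect_lt(abs(r$odds - 10000) / 10000, 0.02)
  expect_error(spontaneous_rate_survey(2, 0, 2), "positive")
})

test_that("density-based rate returns the unrounded value", {
  r <- spontaneous_rate_density(3.69, 3, 20000)
  expect_equal(r$rate_pct_per_day, 3.69 / 20000 * 8 * 100)
  expect_equal(round(r$rate_pct_per_day, 4), 0.1476)
  expect_equal(spontaneous_rate_density(0, 3, 20000)$rate_pct_per_day, 0)
  r2 <- spontaneous_rate_density(3.69, 3, 40000)
  expect_equal(r2$rate_pct_per_day, r$rate_pct_per_day / 2)
  expect_error(spontaneous_rate_density(3.69, 3, 0), "positive")
})

test_that("branch-order risks redistribute the overall rate by g/f", {
  bt <- branch_order_risks(c(0.5, 0.5), c(0.8, 0.2), 0.00118)
  expect_equal(bt$r, c(0.001888, 0.000472))
  expect_equal(sum(bt$f * bt$r), 0.00118)
  # g proportional to f -> uniform risk
  btu <- branch_order_risks(c(0.3, 0.7), c(0.3, 0.7), 0.002)
  expect_equal(btu$r, c(0.002, 0.002))
  expect_error(branch_order_risks(c(1, 0), c(0.5, 0.5), 0.001),
               "no capillaries")
  expect_error(branch_order_risks(c(0.5, 0.4), c(0.5, 0.5), 0.001), "sum to 1")
})

test_that("sum(f * r) = R to 1e-12 for random normalized tables", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(3:9, 1)
    f <- runif(k); f <- f / sum(f)
    g <- runif(k); g <- g / sum(g)
    R <- runif(1, 1e-5, 1e-2)
    bt <- branch_order_risks(f, g, R)
    expect_lt(abs(sum(bt$f * bt$r) - R), 1e-12)
    expect_true(all(bt$r >= 0))
  }
})

test_that("risk-weighted obstruction sampling recovers g on large populations", {
  bt <- default_branch_order_table()
  set.seed(12)
  n <- 400000
  orders <- sample(bt$order, n, replace = TRUE, prob = bt$f)
  risk <- bt$r[match(orders, bt$order)]
  obstructed <- runif(n) < risk * 50  # scale up the rate for sampling power
  g_hat <- tabulate(orders[obstructed], nbins = max(bt$order))
  g_hat <- g_hat / sum(g_hat)
  expect_lt(max(abs(g_hat[bt$order] - bt$g)), 0.02)
})

test_that("densities normalize to cohort controls and average across cohorts", {
  r1 <- normalized_density(4, 1, c(8, 8), 1)
  expect_equal(r1$grand_mean, 0.5)
  r2 <- normalized_density(6, 1, c(6, 6), 1)
  expect_equal(r2$grand_mean, 1)
  r3 <- normalized_density(c(4, 6), c("a", "b"), c(10, 10), c("a", "b"))
  expect_equal(r3$grand_mean, 0.5)
  expect_error(normalized_density(4, "a", c(8, 8), "b"), "without control")
})

test_that("whole-cortex extrapolation multiplies volume by density", {
  expect_equal(total_capillary_pool(180, 20000), 3.6e6)
  expect_equal(total_capillary_pool(1, 20000), 20000)
})
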