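# Synthetic-data generators: ground truth, determinism, and contracts.

test_that("vessel-stack truth reports exact analytic geometry", {
  sp <- cylinder_spec(c(10, 10, 3), c(10, 10, 78), 2)
  out <- generate_vessel_stack(list(sp), synth_config(dims = c(40, 40, 42)))
  expect_equal(out$truth$n_vessels, 1)
  expect_equal(out$truth$total_length, 75)
  expect_equal(out$truth$total_volume, pi * 4 * 75)
  expect_equal(round(out$truth$total_volume, 2), 942.48)
})

test_that("empty spec list yields an all-background stack with zero truth", {
  cfg <- synth_config(dims = c(16, 16, 6), blur_sigma_um = 0)
  out <- generate_vessel_stack(list(), cfg)
  expect_true(all(out$stack$data == cfg$background))
  expect_equal(out$truth$n_vessels, 0)
  expect_equal(out$truth$total_volume, 0)
})

test_that("truth is geometry only: noise and blur settings do not change it", {
  sp <- cylinder_spec(c(10, 10, 3), c(10, 12, 60), 2)
  base <- generate_vessel_stack(list(sp), synth_config(dims = c(40, 40, 35)))
  noisy <- generate_vessel_stack(list(sp),
    synth_config(dims = c(40, 40, 35), blur_sigma_um = 1,
                 shot_scale = 2, read_noise_sd = 20, seed = 1))
  expect_equal(noisy$truth$total_volume, base$truth$total_volume)
  expect_equal(noisy$truth$total_length, base$truth$total_length)
})

test_that("same specs and seed give bit-identical stacks; cylinders outside bounds are rejected", {
  sp <- cylinder_spec(c(10, 10, 3), c(10, 10, 50), 2)
  cfg <- synth_config(dims = c(32, 32, 30), shot_scale = 2,
                      read_noise_sd = 3, seed = 77)
  a <- generate_vessel_stack(list(sp), cfg)
  b <- generate_vessel_stack(list(sp), cfg)
  expect_identical(a$stack$data, b$stack$data)
  bad <- cylinder_spec(c(10, 10, 3), c(500, 10, 50), 2)
  expect_error(generate_vessel_stack(list(bad), cfg), "outside the stack")
})

test_that("cylinder specs validate their invariants", {
  expect_error(cylinder_spec(c(0, 0, 0), c(0, 0, 0), 2), "differ")
  expect_error(cylinder_spec(c(0, 0, 0), c(1, 0, 0), 0), "radius")
})

test_that("line-scan streaks move by velocity * line_period per line", {
  v <- 500; lp <- 1; pp <- 2
  ls <- generate_linescan(v, lp, pp, n_lines = 64, n_pixels = 64, seed = 1)
  dpx_true <- v * (lp / 1000) / pp
  # cross-correlate consecutive lines at the expected displacement
  D <- max(ls$img) - ls$img
  best <- sapply(1:40, function(j) {
    sh <- sapply(seq(-2, 2, by = 0.25), function(d) {
      x <- seq_len(64)
      sum(D[j, ] * approx(x - d, D[j + 8, ], xout = x, rule = 2)$y)
    })
    seq(-2, 2, by = 0.25)[which.max(sh)]
  })
  expect_equal(median(best) / 8, dpx_true, tolerance = 0.15)
})

test_that("zero velocity yields constant streak columns; aliasing errors", {
  ls0 <- generate_linescan(0, 1, 2, n_lines = 32, n_pixels = 48, seed = 2)
  expect_true(all(apply(ls0$img, 2, function(col) diff(range(col))) < 1e-9))
  expect_error(generate_linescan(2e8, 1, 2, n_pixels = 32), "aliasing")
})

test_that("line-scan metadata is stored verbatim (30.83 ms full scan, 2 um/pixel)", {
  n_lines <- 64
  lp <- 30.83 / n_lines
  ls <- generate_linescan(300, lp, 2, n_lines = n_lines, seed = 1)
  expect_equal(ls$line_period_ms, lp)
  expect_equal(ls$line_period_ms * n_lines, 30.83)
  expect_equal(ls$pixel_pitch_um, 2)
})

test_that("fate generator respects degenerate and quota compositions", {
  ft0 <- generate_fate_table(n_tracks = 60, p_prune = 0, p_angiophagy = 0,
                             seed = 4)
  term <- ft0[ft0$time_day == 21, ]
  expect_equal(sum(term$status == "pruned"), 0)
  ftq <- generate_fate_table(quota = c(pruned = 49, washout = 110,
                                       angiophagy = 3), seed = 5)
  s <- summarize_fates(ftq, 21)
  expect_equal(s$n_pruned, 49)
  expect_equal(s$n_washout, 110)
  expect_equal(s$n_angiophagy, 3)
})

test_that("pruned fraction converges to p_prune (binomial oracle)", {
  n <- 1000; p <- 0.30
  ft <- generate_fate_table(n_tracks = n, p_prune = p, p_angiophagy = 0.02,
                            seed = 6)
  term <- ft[ft$time_day == 21, ]
  frac <- mean(term$status == "pruned")
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("fate generator validates its inputs", {
  expect_error(generate_fate_table(timepoints = numeric(0)), "empty")
  expect_error(generate_fate_table(p_prune = 0.8, p_angiophagy = 0.5),
               "<= 1")
})

test_that("fate trajectories are internally consistent", {
  ft <- generate_fate_table(seed = 8)
  for (tt in split(ft, ft$track)) {
    tt <- tt[order(tt$time_day), ]
    expect_equal(tt$status[1], "obstructed")
    # once pruned, always pruned
    pr <- which(tt$status == "pruned")
    if (length(pr)) expect_equal(pr, seq(min(pr), nrow(tt)))
    # a route implies the track regained flow at some point
    if (tt$route[1] %in% c("washout", "angiophagy")) {
      expect_true(any(tt$status == "flowing"))
    }
  }
})

test_that("coverage quota fixture places exactly the requested pixel counts", {
  p0 <- generate_coloc_projection(1, 0, dims = c(50, 20))
  expect_equal(sum(p0$signal_mask), 0)
  p100 <- generate_coloc_projection(1, 100, dims = c(50, 20))
  expect_true(all(p100$signal_mask[p100$vessel_mask]))
  # 1000-pixel mask at 20% -> exactly 200 signal pixels, all on the mask
  p20 <- generate_coloc_projection(1, 20, seed = 3, dims = c(50, 20))
  expect_equal(sum(p20$vessel_mask), 1000)
  expect_equal(sum(p20$signal_mask), 200)
  expect_true(all(p20$vessel_mask[p20$signal_mask]))
  expect_error(generate_coloc_projection(1, 120), "\\[0, 100\\]")
})

test_that("stack and line-scan text round trips preserve data and calibration", {
  out <- generate_vessel_stack(
    list(cylinder_spec(c(10, 10, 3), c(10, 10, 40), 2)),
    synth_config(dims = c(24, 24, 24), read_noise_sd = 2, seed = 9))
  f <- tempfile(fileext = ".csv")
  write_stack_text(out$stack, f)
  back <- read_stack_text(f)
  expect_equal(back$data, out$stack$data, tolerance = 1e-10)
  expect_equal(back$voxel_size_um, out$stack$voxel_size_um)
  ls <- generate_linescan(400, 1, 2, n_lines = 32, n_pixels = 32, seed = 10)
  f2 <- tempfile(fileext = ".csv")
  write_linescan_text(ls, f2)
  ls2 <- read_linescan_text(f2)
  expect_equal(ls2$img, ls$img, tolerance = 1e-10)
  expect_equal(ls2$line_period_ms, 1)
})
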