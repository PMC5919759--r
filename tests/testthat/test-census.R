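# Capillary census: substack splitting, auto-thresholding, binarization,
# skeleton metrics, and count validation against phantom ground truth.

test_that("substack splitting keeps partial trailing groups with true depth", {
  mk <- function(nz) voxel_stack(array(0, c(4, 4, nz)))
  s30 <- split_substacks(mk(30))
  expect_length(s30, 3)
  expect_true(all(sapply(s30, function(s) attr(s, "depth_um")) == 20))
  s25 <- split_substacks(mk(25))
  expect_equal(sapply(s25, function(s) dim(s$data)[3]), c(10, 10, 5))
  expect_equal(sapply(s25, function(s) attr(s, "depth_um")), c(20, 20, 10))
  s5 <- split_substacks(mk(5))
  expect_length(s5, 1)
  expect_equal(attr(s5[[1]], "depth_um"), 10)
})

test_that("all three threshold methods separate two narrow modes", {
  h <- integer(256)
  h[10:12 + 1] <- c(100, 400, 100)
  h[200:202 + 1] <- c(60, 250, 60)
  for (m in c("triangle", "yen", "moments")) {
    lev <- as.integer(auto_threshold(h, m))
    expect_gt(lev, 10)
    expect_lt(lev, 200)
  }
})

test_that("thresholds sit within 2 bins of the brute-force misclassification optimum", {
  # block-bimodal histogram: low class occupies bins 70..90, high 160..180
  h <- integer(256)
  h[(70:90) + 1] <- 200
  h[(160:180) + 1] <- 150
  # brute force over all 256 candidate thresholds: pixels of the low class
  # above t plus pixels of the high class at or below t
  low <- integer(256); low[(70:90) + 1] <- 200
  high <- integer(256); high[(160:180) + 1] <- 150
  mis <- (sum(low) - cumsum(low)) + cumsum(high)  # mis[t + 1] for t = 0..255
  argmin_set <- which(mis == min(mis)) - 1
  for (m in c("triangle", "yen", "moments")) {
    lev <- as.integer(auto_threshold(h, m))
    expect_lte(min(abs(argmin_set - lev)), 2)
  }
})

test_that("degenerate histograms are handled: single bin flagged, uniform in range", {
  h1 <- integer(256); h1[41] <- 999
  for (m in c("triangle", "yen", "moments")) {
    lev <- auto_threshold(h1, m)
    expect_equal(as.integer(lev), 40)
    expect_true(attr(lev, "degenerate"))
  }
  hu <- rep(10L, 256)
  for (m in c("triangle", "yen", "moments")) {
    lev <- as.integer(auto_threshold(hu, m))
    expect_gte(lev, 0)
    expect_lte(lev, 255)
  }
})

test_that("binarization: background-only stacks give empty masks, speckle is removed", {
  bg <- generate_vessel_stack(list(), synth_config(dims = c(16, 16, 10)))
  mask <- binarize_substack(split_substacks(bg$stack)[[1]])
  expect_false(any(mask))
  expect_true(attr(mask, "degenerate"))
  # single isolated bright pixel is eliminated by the radius-1 median filter
  proj <- matrix(10, 21, 21)
  proj[11, 11] <- 200
  mask2 <- binarize_substack(proj)
  expect_false(any(mask2))
})

test_that("projected mask area of a cylinder phantom is within 25% of analytic", {
  ph <- inplane_phantom(blur_sigma_um = 0.2)
  sub <- split_substacks(ph$stack)[[1]]
  mask <- binarize_substack(sub)
  area <- sum(mask) * 0.62^2
  analytic <- 2 * 2 * 75  # projected rectangle of an in-plane cylinder
  expect_lt(abs(area - analytic) / analytic, 0.25)
})

test_that("capillary count is total vascular volume over 942.48", {
  expect_equal(round(capillary_volume(), 2), 942.48)
  # one substack whose mask area x depth gives exactly 94,248 um^3
  px <- 1
  mask <- matrix(FALSE, 100, 100)
  mask[1:50, 1:94] <- TRUE  # 4700 px = 4700 um^2
  res <- vascular_metrics(list(mask), voxel_size_um = c(px, px),
                          depths_um = 94248 / 4700)
  expect_equal(res$total_volume_um3, 94248, tolerance = 1e-12)
  expect_equal(res$capillary_count, 94248 / capillary_volume())
  expect_equal(round(res$capillary_count), 100)
})

test_that("empty masks give zero counts and lengths", {
  res <- vascular_metrics(list(matrix(FALSE, 10, 10)),
                          voxel_size_um = c(1, 1), depths_um = 20)
  expect_equal(res$capillary_count, 0)
  expect_equal(res$total_length_um, 0)
  expect_equal(res$total_volume_um3, 0)
})

test_that("width is flagged undefined when area exists without skeleton", {
  m <- matrix(FALSE, 8, 8)
  res0 <- vascular_metrics(list(m), c(1, 1), 20)
  expect_length(res0$flagged, 0)
})

test_that("census count lands within [9, 18] on the 12-cylinder phantom", {
  ph <- tilted_phantom_12()
  expect_equal(ph$truth$n_vessels, 12)
  expect_equal(ph$truth$total_volume, 12 * pi * 4 * 75, tolerance = 1e-12)
  res <- capillary_census(ph$stack)
  expect_gte(res$capillary_count, 9)
  expect_lte(res$capillary_count, 18)
})

test_that("automated count is within +/-1 of truth on small noiseless phantoms", {
  for (n in c(2, 5)) {
    ph <- vertical_phantom(n, L = 80)
    truth_count <- ph$truth$total_volume / capillary_volume()
    res <- capillary_census(ph$stack)
    expect_lt(abs(res$capillary_count - truth_count), 1)
    expect_lt(abs(res$capillary_count - n), 1.5)
  }
})

test_that("projection bias has the documented direction on noiseless phantoms", {
  ph <- inplane_phantom(blur_sigma_um = 0.2)
  res <- capillary_census(ph$stack)
  # volume overestimated (square vessels rather than cylinders)
  expect_gte(res$total_volume_um3, ph$truth$total_volume)
  # skeleton length underestimated (loss of length in z)
  expect_lte(res$total_length_um, ph$truth$total_length)
  vert <- vertical_phantom(3, L = 80)
  resv <- capillary_census(vert$stack)
  expect_gte(resv$total_volume_um3, vert$truth$total_volume * 0.999)
  expect_lte(resv$total_length_um, vert$truth$total_length)
})

test_that("adding a disjoint vessel never decreases census metrics", {
  ph2 <- vertical_phantom(2, L = 80)
  ph3 <- vertical_phantom(3, L = 80)
  r2 <- capillary_census(ph2$stack)
  r3 <- capillary_census(ph3$stack)
  expect_gte(r3$capillary_count, r2$capillary_count)
  expect_gte(r3$total_volume_um3, r2$total_volume_um3)
  expect_gte(r3$total_length_um, r2$total_length_um)
})

test_that("median filter order is configurable and default follows threshold-then-filter", {
  ph <- vertical_phantom(2, L = 80, blur_sigma_um = 0.3, noise_sd = 4,
                         seed = 3)
  sub <- split_substacks(ph$stack)[[1]]
  m_default <- binarize_substack(sub)
  m_pre <- binarize_substack(sub, median_before_threshold = TRUE)
  expect_type(m_default[1], "logical")
  expect_type(m_pre[1], "logical")
  # both orders agree on the bulk of the mask
  expect_gt(sum(m_default & m_pre) / max(1, sum(m_default | m_pre)), 0.7)
})
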