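test_that("the 2D Gaussian fit recovers a noiseless rendered spot exactly", {
  sp <- render_spot_volume(amplitude = 5000, sd_xy = 120)
  fit <- fit_gaussian_spot(sp$vol, sp$center)
  expect_true(fit$converged)
  expect_lt(abs(fit$amplitude - 5000), 1)
  expect_lt(abs(fit$sd_nm - 120), 1)
  expect_lt(abs(fit$center_nm[["x"]] - sp$center[1]), 1)
})

test_that("a flat image yields no spot", {
  vol <- image_volume(array(100, dim = c(3, 11, 11)))
  fit <- fit_gaussian_spot(vol, c(700, 700, 300))
  expect_true(!fit$converged || fit$amplitude < 1e-6)
  expect_error(fit_gaussian_spot(vol, c(1e6, 1e6, 0)), "bounds")
})

test_that("the fit lands in the same basin as a brute-force grid-search oracle", {
  set.seed(21)
  sp <- render_spot_volume(amplitude = 3000, sd_xy = 150, offset = 200,
                           dim_px = c(7, 13, 13),
                           center = c(870, 850, 900))
  noisy <- sp$vol
  noisy$voxels <- kinspa:::apply_camera_noise(noisy$voxels, gain = 2,
                                              read_sd = 15)
  fit <- fit_gaussian_spot(noisy, sp$center)
  # exhaustive grid search over (amplitude, x, y, sd) on a coarse lattice
  # covering the whole fitted slice, offset fixed at the median: an
  # independent minimizer
  ax <- volume_axes(noisy)
  sl <- noisy$voxels[round(fit$center_nm[["z"]] / noisy$pitch_z) + 1, , ]
  off <- stats::median(sl)
  X <- matrix(ax$x, nrow = length(ax$y), ncol = length(ax$x), byrow = TRUE)
  Y <- matrix(ax$y, nrow = length(ax$y), ncol = length(ax$x))
  grid <- expand.grid(a = seq(2000, 4000, by = 100),
                      x0 = seq(700, 1000, by = 35),
                      y0 = seq(700, 1000, by = 35),
                      s = seq(100, 220, by = 10))
  rss <- mapply(function(a, x0, y0, s)
    sum((off + a * exp(-((X - x0)^2 + (Y - y0)^2) / (2 * s^2)) - sl)^2),
    grid$a, grid$x0, grid$y0, grid$s)
  best <- grid[which.min(rss), ]
  expect_lt(abs(fit$center_nm[["x"]] - best$x0), 35)
  expect_lt(abs(fit$center_nm[["y"]] - best$y0), 35)
  expect_lt(abs(fit$sd_nm - best$s), 20)
  # the continuous fit must be at least as good as the lattice optimum
  expect_lte(fit$rss, min(rss) * 1.01)
})

test_that("the declustering size filter is strict at the 245-nm boundary", {
  spots <- lapply(c(120, 244.9, 245.0, 300), mock_spot)
  kept <- filter_spots_by_size(spots)
  expect_equal(vapply(kept, `[[`, 0, "sd_nm"), c(120, 244.9))
  expect_equal(filter_spots_by_size(list()), list())
  same <- lapply(rep(100, 4), mock_spot)
  expect_equal(filter_spots_by_size(same), same)
})

test_that("raising the size cutoff never removes a previously kept spot", {
  set.seed(4)
  spots <- lapply(stats::runif(40, 50, 400), mock_spot)
  for (i in 1:10) {
    t1 <- sort(stats::runif(2, 60, 390))
    k1 <- filter_spots_by_size(spots, t1[1])
    k2 <- filter_spots_by_size(spots, t1[2])
    expect_true(all(vapply(k1, `[[`, 0, "sd_nm") %in%
                      vapply(k2, `[[`, 0, "sd_nm")))
  }
})

test_that("power scaling and normalized intensity follow their definitions", {
  expect_equal(apply_power_scaling(1000, calibration_standard(50, 2)),
               2000)
  expect_equal(apply_power_scaling(1000, calibration_standard(50, 1)),
               1000)
  expect_equal(normalized_intensity(5000, 1000), 5)
  expect_equal(normalized_intensity(5000, 10000), 0.5)
  expect_equal(normalized_intensity(0, 1000), 0)
  expect_error(normalized_intensity(5000, 500), "divisor")
})

test_that("quantifying a half-power image scaled by its power ratio matches full power", {
  full <- calibration_standard(100, power_ratio = 1)
  half <- calibration_standard(100, power_ratio = 2)
  sf <- simulate_cluster_spot(4, calib = full, noise = FALSE, seed = 7)
  sh <- simulate_cluster_spot(4, calib = half, noise = FALSE, seed = 7)
  af <- fit_gaussian_spot(sf$volume, sf$truth$center_nm)$amplitude
  ah <- fit_gaussian_spot(sh$volume, sh$truth$center_nm)$amplitude
  expect_equal(copies_from_amplitude(ah, half)$copies_total,
               copies_from_amplitude(af, full)$copies_total,
               tolerance = 1e-6)
})

test_that("copy numbers derive linearly from calibrated amplitudes", {
  calib <- calibration_standard(100)
  cp <- copies_from_amplitude(64 * 100, calib)
  expect_equal(cp$copies_total, 64)
  expect_equal(cp$copies_per_kinetochore, 4)
  expect_equal(copies_from_amplitude(0, calib)$copies_total, 0)
})

test_that("per-kinetochore counts of 1 and 4 are distinguished at default noise", {
  calib <- calibration_standard(100)
  est <- function(cp, seed) {
    s <- simulate_cluster_spot(cp, calib = calib, seed = seed)
    f <- fit_gaussian_spot(s$volume, s$truth$center_nm)
    copies_from_amplitude(f$amplitude, calib)$copies_per_kinetochore
  }
  one <- vapply(1:60, function(i) est(1, 100 + i), 0)
  four <- vapply(1:60, function(i) est(4, 200 + i), 0)
  calls <- c(one < 2.5, four >= 2.5)
  expect_gte(mean(calls), 0.99)
})

test_that("anaphase/G1 ratios propagate first-order errors", {
  r <- anaphase_g1_ratio(rep(2, 5), rep(1, 5))
  expect_equal(r$ratio, 2)
  expect_equal(r$se, 0)
  x <- c(1.1, 0.9, 1.2, 1.0)
  expect_equal(anaphase_g1_ratio(x, x)$ratio, 1)
  expect_error(anaphase_g1_ratio(numeric(0), 1), "non-empty")
  expect_error(anaphase_g1_ratio(c(1, 2), c(0, 0)), "zero G1")
  # SE -> 0 as within-group variance -> 0
  ses <- vapply(c(0.2, 0.02, 0.002), function(s) {
    set.seed(1)
    anaphase_g1_ratio(stats::rnorm(50, 2, s), stats::rnorm(50, 1, s))$se
  }, 0)
  expect_true(all(diff(ses) < 0))
})

test_that("the propagated SE gives near-nominal coverage for a true ratio of 2", {
  set.seed(42)
  hits <- vapply(1:100, function(i) {
    a <- stats::rnorm(150, 2, 0.5)
    g <- stats::rnorm(150, 1, 0.3)
    r <- anaphase_g1_ratio(a, g)
    abs(r$ratio - 2) <= 2 * r$se
  }, logical(1))
  expect_gte(sum(hits), 93)
})

test_that("cluster separation equals direct coordinate arithmetic", {
  a <- mock_spot(100, center = c(x = 0, y = 0, z = 0))
  expect_equal(cluster_separation(a, a), 0)
  b <- mock_spot(100, center = c(x = 0, y = 2000, z = 0))
  expect_equal(cluster_separation(a, b), 2000)
  set.seed(8)
  for (i in 1:5) {
    p <- stats::rnorm(3, 0, 500); q <- stats::rnorm(3, 0, 500)
    sa <- mock_spot(100, center = stats::setNames(p, c("x", "y", "z")))
    sb <- mock_spot(100, center = stats::setNames(q, c("x", "y", "z")))
    expect_equal(cluster_separation(sa, sb), sqrt(sum((p - q)^2)))
  }
  bad <- mock_spot(100); bad$converged <- FALSE
  expect_error(cluster_separation(a, bad), "converged")
})
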