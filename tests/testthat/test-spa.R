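test_that("the fiducial pair fit recovers two noiseless spots and their separation", {
  pop <- simulate_particle_population(1, "metaphase", rotation = 0.4,
                                      spindle_length_range = c(1500, 1500),
                                      noise = FALSE, seed = 1)
  tr <- pop$truth$images
  pair <- fit_fiducial_pair(pop$particles[[1]]$mcherry,
                            c(tr$mother_x + 30, tr$mother_y - 20,
                              tr$mother_z),
                            c(tr$daughter_x - 30, tr$daughter_y + 20,
                              tr$daughter_z))
  expect_lt(abs(pair$spindle_length_nm - 1500), 5)
  # swapped initial guesses give the same pair up to labelling
  sw <- fit_fiducial_pair(pop$particles[[1]]$mcherry,
                          c(tr$daughter_x - 30, tr$daughter_y + 20,
                            tr$daughter_z),
                          c(tr$mother_x + 30, tr$mother_y - 20,
                            tr$mother_z))
  expect_equal(sw$daughter, pair$mother, tolerance = 1)
  expect_equal(sw$mother, pair$daughter, tolerance = 1)
})

test_that("fitted fiducial centres agree with a centre-of-mass oracle on noisy spots", {
  pop <- simulate_particle_population(1, "metaphase", rotation = 1.1,
                                      seed = 6)
  tr <- pop$truth$images
  v <- pop$particles[[1]]$mcherry
  pair <- fit_fiducial_pair(v, c(tr$mother_x + 20, tr$mother_y - 20,
                                 tr$mother_z),
                            c(tr$daughter_x - 20, tr$daughter_y + 20,
                              tr$daughter_z))
  # oracle: background-subtracted centre of mass in a window around the
  # true mother position
  ax <- volume_axes(v)
  wx <- abs(ax$x - tr$mother_x) <= 200
  wy <- abs(ax$y - tr$mother_y) <= 200
  sub <- apply(v$voxels[, wy, wx], c(2, 3), max)
  w <- pmax(sub - stats::median(v$voxels), 0)
  comx <- sum(outer(rep(1, sum(wy)), ax$x[wx]) * w) / sum(w)
  comy <- sum(outer(ax$y[wy], rep(1, sum(wx))) * w) / sum(w)
  expect_lt(abs(pair$mother[["x"]] - comx), v$pitch_xy)
  expect_lt(abs(pair$mother[["y"]] - comy), v$pitch_xy)
})

test_that("phase classification is strict around the 2-um threshold and total", {
  expect_equal(classify_phase(1200), "metaphase")
  expect_equal(classify_phase(3500), "anaphase")
  expect_equal(classify_phase(2000), "metaphase")   # tie to metaphase
  lens <- stats::runif(50, 500, 4000)
  cls <- classify_phase(lens)
  expect_true(all(cls %in% c("metaphase", "anaphase")))
  expect_identical(cls, classify_phase(lens))
})

test_that("realignment centres fiducials to sub-pixel accuracy at any rotation", {
  for (ang in c(0, pi / 6, 2.2)) {
    pop <- simulate_particle_population(1, "metaphase", rotation = ang,
                                        noise = FALSE, seed = 3)
    tr <- pop$truth$images
    pair <- structure(list(
      mother = c(x = tr$mother_x, y = tr$mother_y, z = tr$mother_z),
      daughter = c(x = tr$daughter_x, y = tr$daughter_y,
                   z = tr$daughter_z),
      spindle_length_nm = tr$spindle_length_nm, converged = TRUE),
      class = "fiducial_pair")
    al <- realign_particle(pop$particles[[1]]$mcherry, pair)
    for (side in al) {
      pr <- side$vol$voxels[side$fiducial_index[["z"]], , ]
      pk <- which(pr == max(pr), arr.ind = TRUE)[1, ]
      expect_lte(abs(pk[["row"]] - side$fiducial_index[["y"]]), 1)
      expect_lte(abs(pk[["col"]] - side$fiducial_index[["x"]]), 1)
    }
  }
})

test_that("mother and daughter of a symmetric cell match after the daughter flip", {
  pop <- simulate_particle_population(1, "metaphase", rotation = 0.7,
                                      noise = FALSE, seed = 5)
  tr <- pop$truth$images
  pair <- structure(list(
    mother = c(x = tr$mother_x, y = tr$mother_y, z = tr$mother_z),
    daughter = c(x = tr$daughter_x, y = tr$daughter_y, z = tr$daughter_z),
    spindle_length_nm = tr$spindle_length_nm, converged = TRUE),
    class = "fiducial_pair")
  al <- realign_particle(pop$particles[[1]]$gfp, pair)
  expect_false(al$mother$flipped)
  expect_true(al$daughter$flipped)
  m <- al$mother$vol$voxels[al$mother$fiducial_index[["z"]], , ]
  d <- al$daughter$vol$voxels[al$daughter$fiducial_index[["z"]], , ]
  expect_lt(max(abs(m - d)) / max(m), 0.03)
})

test_that("mirror-averaged images equal their own mirror bit-exactly", {
  rt <- spa_roundtrip("metaphase", n_images = 4, seed = 13, n_mc = 0)
  img <- rt$spa$img
  expect_identical(img, img[, rev(seq_len(ncol(img)))])
})

test_that("averaging N copies of one particle equals the single particle", {
  pop <- simulate_particle_population(1, "metaphase", seed = 8)
  an <- population_annotations(pop)
  pair <- fit_fiducial_pair(pop$particles[[1]]$mcherry,
                            c(an$mother_x, an$mother_y, an$mother_z),
                            c(an$daughter_x, an$daughter_y, an$daughter_z))
  al <- realign_particle(pop$particles[[1]]$gfp, pair)
  one <- average_particles(al["mother"])
  many <- average_particles(rep(al["mother"], 4))
  expect_equal(many$img, one$img, tolerance = 1e-12)
  expect_equal(many$n_images, 4L)
})

test_that("the averaged profile peaks at the generator's fiducial-cluster offset", {
  rt <- spa_roundtrip("anaphase", n_images = 12, seed = 17, n_mc = 0)
  expect_lt(abs(rt$fit$center_nm - rt$truth$cluster_offset),
            rt$spa$pitch_nm * 8)   # one raw pixel
})

test_that("the vertical profile fit recovers centre and width of a clean blob", {
  # symmetric Gaussian blob placed exactly at the fiducial position
  ys <- seq(-600, 600, by = 5)
  img <- outer(exp(-ys^2 / (2 * fwhm_to_sigma(200)^2)),
               exp(-seq(-300, 300, by = 5)^2 / (2 * 150^2))) + 0.01
  spa <- structure(list(img = img, ys_nm = ys,
                        xs_nm = seq(-300, 300, by = 5), pitch_nm = 5,
                        n_images = 1L, upscale = 1L, mirrored = TRUE,
                        phase = NA_character_),
                   class = "spa_image")
  fit <- vertical_profile_fit(spa, n_mc = 0)
  expect_lt(abs(fit$center_nm), 2)
  expect_lt(abs(fit$fwhm_nm - 200), 10)
  expect_true(fit$converged)
})

test_that("Monte Carlo SEs vanish with the residuals and scale with noise", {
  set.seed(2)
  x <- seq(-500, 500, 10)
  clean <- 5 * exp(-x^2 / (2 * 150^2)) + 0.2
  refit_factory <- function() {
    function(y) {
      f <- kinspa:::gauss1d_fit(x, y)
      if (!f$converged) stop("refit failed")
      f$par
    }
  }
  se0 <- mc_parameter_errors(refit_factory(), clean, rep(0, length(x)),
                             n = 20, seed = 1)
  expect_true(all(se0 < 1e-9))
  y1 <- clean + stats::rnorm(length(x), 0, 0.05)
  f1 <- kinspa:::gauss1d_fit(x, y1)
  se1 <- mc_parameter_errors(refit_factory(), f1$fitted, f1$residuals,
                             n = 60, seed = 2)
  y2 <- clean + stats::rnorm(length(x), 0, 0.1)
  f2 <- kinspa:::gauss1d_fit(x, y2)
  se2 <- mc_parameter_errors(refit_factory(), f2$fitted, f2$residuals,
                             n = 60, seed = 3)
  ratio <- se2[["sd"]] / se1[["sd"]]
  expect_gt(ratio, 2 * 0.8)
  expect_lt(ratio, 2 * 1.2)
})

test_that("Monte Carlo SEs agree with linearized least-squares errors within 2x", {
  set.seed(9)
  x <- seq(-500, 500, 10)
  truth <- c(amplitude = 5, center = 20, sd = 150, offset = 0.2)
  y <- truth[["offset"]] + truth[["amplitude"]] *
    exp(-(x - truth[["center"]])^2 / (2 * truth[["sd"]]^2)) +
    stats::rnorm(length(x), 0, 0.05)
  f <- kinspa:::gauss1d_fit(x, y)
  refit <- function(yy) {
    ff <- kinspa:::gauss1d_fit(x, yy, init = f$par)
    if (!ff$converged) stop("refit failed")
    ff$par
  }
  se_mc <- mc_parameter_errors(refit, f$fitted, f$residuals, n = 100,
                               seed = 4)
  # analytic oracle: SE from the Jacobian of the model at the optimum
  p <- f$par
  g <- exp(-(x - p[["center"]])^2 / (2 * p[["sd"]]^2))
  J <- cbind(amplitude = g,
             center = p[["amplitude"]] * g * (x - p[["center"]]) /
               p[["sd"]]^2,
             sd = p[["amplitude"]] * g * (x - p[["center"]])^2 /
               p[["sd"]]^3,
             offset = 1)
  s2 <- sum(f$residuals^2) / (length(x) - 4)
  se_lin <- sqrt(diag(solve(crossprod(J))) * s2)
  for (nm in names(se_lin)) {
    expect_gt(se_mc[[nm]] / se_lin[[nm]], 0.5)
    expect_lt(se_mc[[nm]] / se_lin[[nm]], 2)
  }
})

test_that("fiducial-corrected distances remove a built-in channel shift", {
  shift <- 30
  mk_fit <- function(center) {
    f <- list(center_nm = center)
    class(f) <- "profile_fit"
    f
  }
  # green-channel protein at 250 nm, green fiducial image shifted by
  # +30 nm relative to the red fiducial frame
  protein <- mk_fit(250 + shift)
  reference <- mk_fit(0)
  correction <- -shift   # measured from a dual-channel calibration pair
  expect_equal(fiducial_corrected_distance(protein, reference,
                                           correction), 250)
  expect_equal(fiducial_corrected_distance(protein, reference), 280)
  expect_equal(fiducial_corrected_distance(reference, reference), 0)
})

test_that("75% contours outline blobs with the analytic level-set area", {
  s <- 120
  ys <- seq(-500, 500, by = 10)
  xs <- seq(-500, 500, by = 10)
  img <- outer(exp(-ys^2 / (2 * s^2)), exp(-xs^2 / (2 * s^2)))
  spa <- structure(list(img = img, ys_nm = ys, xs_nm = xs, pitch_nm = 10,
                        n_images = 1L, upscale = 1L, mirrored = TRUE,
                        phase = NA_character_),
                   class = "spa_image")
  cm <- contour_75(spa)
  expect_length(cm$polygons, 1L)
  area <- kinspa:::polygon_area(cm$polygons[[1]]$x_nm,
                                cm$polygons[[1]]$y_nm)
  expect_lt(abs(area - pi * 2 * log(4 / 3) * s^2) /
              (pi * 2 * log(4 / 3) * s^2), 0.05)
  # two well-separated blobs give two polygons
  img2 <- outer(exp(-(ys - 300)^2 / (2 * 60^2)) +
                  exp(-(ys + 300)^2 / (2 * 60^2)),
                exp(-xs^2 / (2 * 60^2)))
  spa2 <- spa; spa2$img <- img2
  expect_length(contour_75(spa2)$polygons, 2L)
})

test_that("pipeline output is invariant to a global in-plane rotation of the inputs", {
  base <- spa_roundtrip("metaphase", n_images = 6, seed = 23, n_mc = 0,
                        rotation = 0.3)
  rot <- spa_roundtrip("metaphase", n_images = 6, seed = 23, n_mc = 0,
                       rotation = 0.3 + pi / 3)
  expect_lt(abs(base$fit$fwhm_nm - rot$fit$fwhm_nm), 6)
  expect_lt(abs(base$fit$center_nm - rot$fit$center_nm), 6)
})
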