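# Shared fixture builders. Everything is generated in code at test time.

# Noiseless volume holding one symmetric Gaussian spot.
render_spot_volume <- function(amplitude = 5000, sd_xy = 120, sd_z = 300,
                               offset = 100, pitch_xy = 140,
                               pitch_z = 300, dim_px = c(7, 21, 21),
                               center = NULL) {
  axes <- list(x = (seq_len(dim_px[3]) - 1) * pitch_xy,
               y = (seq_len(dim_px[2]) - 1) * pitch_xy,
               z = (seq_len(dim_px[1]) - 1) * pitch_z)
  if (is.null(center))
    center <- c(mean(range(axes$x)), mean(range(axes$y)),
                axes$z[(dim_px[1] + 1) %/% 2])
  vox <- array(offset, dim = dim_px)
  vox <- kinspa:::add_gaussian_blob(vox, axes, center, amplitude,
                                    c(sd_xy, sd_xy, sd_z))
  list(vol = image_volume(vox, pitch_xy, pitch_z), center = center)
}

# Mock spot_fit with a given SD, for filter tests.
mock_spot <- function(sd_nm, amplitude = 1000,
                      center = c(x = 0, y = 0, z = 0)) {
  structure(list(center_nm = center, amplitude = amplitude, sd_nm = sd_nm,
                 offset = 0, rss = 0, converged = TRUE),
            class = "spot_fit")
}

# Annotated initial guesses (truth + fixed jitter) for a simulated
# population, as spa_average_population expects.
population_annotations <- function(pop, jitter = 25) {
  tr <- pop$truth$images
  data.frame(mother_x = tr$mother_x + jitter,
             mother_y = tr$mother_y - jitter,
             mother_z = tr$mother_z,
             daughter_x = tr$daughter_x - jitter,
             daughter_y = tr$daughter_y + jitter,
             daughter_z = tr$daughter_z)
}

# Full SPA-SIM round trip on one synthetic population: returns the
# vertical profile fit of the averaged image.
spa_roundtrip <- function(phase, n_images = 24, seed = 1, n_mc = 100,
                          ...) {
  pop <- simulate_particle_population(n_images, phase, seed = seed, ...)
  res <- spa_average_population(pop$particles,
                                population_annotations(pop))
  list(fit = vertical_profile_fit(res$spa, n_mc = n_mc, seed = seed + 1),
       truth = pop$truth, spa = res$spa)
}
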