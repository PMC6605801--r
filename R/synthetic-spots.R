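# Synthetic generators for diffraction-limited spot images, two-channel
# particle populations, and camera noise. These emulate the statistical
# structure of the real acquisitions (Gaussian spots on a dark background,
# Poisson photon noise plus Gaussian read noise, paired SPB fiducials
# defining a spindle axis) so every analysis stage can be validated by
# round trips against known ground truth.

# Add an anisotropic 3D Gaussian blob to a voxel array. `axes` gives the
# physical coordinates (nm) of voxel centres; `theta` rotates the (sx, sy)
# lateral axes in the x-y plane (u along the rotated x axis).
add_gaussian_blob <- function(vox, axes, center, amplitude, sigma,
                              theta = 0) {
  s <- rep(sigma, length.out = 3)
  dx <- axes$x - center[1]
  dy <- axes$y - center[2]
  gz <- exp(-(axes$z - center[3])^2 / (2 * s[3]^2))
  ct <- cos(theta); st <- sin(theta)
  U <- outer(dy * st, dx * ct, `+`)       # (ny, nx) axis-aligned coordinate
  V <- outer(dy * ct, -dx * st, `+`)
  plane <- amplitude * exp(-U^2 / (2 * s[1]^2) - V^2 / (2 * s[2]^2))
  for (iz in seq_along(axes$z))
    vox[iz, , ] <- vox[iz, , ] + gz[iz] * plane
  vox
}

# EMCCD/sCMOS-style camera noise: Poisson photon noise at the given gain
# (camera units per photon) followed by zero-mean Gaussian read noise.
# Negative values are clipped at zero (intensities are non-negative).
apply_camera_noise <- function(vox, gain = 1, read_sd = 0) {
  n <- length(vox)
  out <- stats::rpois(n, pmax(vox, 0) / gain) * gain
  if (read_sd > 0) out <- out + stats::rnorm(n, 0, read_sd)
  array(pmax(out, 0), dim = dim(vox))
}

#' Single-GFP brightness calibration standard
#'
#' The predicted image amplitude of a single GFP molecule under the
#' imaging configuration, derived from a cytosolic-GFP strain whose
#' concentration was measured by fluorescence correlation spectroscopy.
#' When a dim sample is imaged at reduced laser power, its images are
#' multiplied by `power_ratio` before comparison with this standard.
#'
#' @param single_gfp_amplitude amplitude (camera units) of one GFP, > 0.
#' @param power_ratio laser power ratio (calibration / acquisition), >= 1.
#' @return An object of class `calibration_standard`.
#' @export
calibration_standard <- function(single_gfp_amplitude, power_ratio = 1) {
  if (!is.numeric(single_gfp_amplitude) || single_gfp_amplitude <= 0)
    stop("single_gfp_amplitude must be > 0")
  if (power_ratio < 1) stop("power_ratio must be >= 1")
  structure(list(single_gfp_amplitude = single_gfp_amplitude,
                 power_ratio = power_ratio),
            class = "calibration_standard")
}

#' Simulate a clustered-kinetochore spot image
#'
#' Renders one diffraction-limited Gaussian spot whose amplitude encodes
#' the total GFP copy number of a clustered kinetochore (copies per
#' kinetochore times kinetochores per cluster times the single-GFP
#' amplitude, attenuated by the calibration `power_ratio` when imaging at
#' reduced power), on a constant background, with optional Poisson +
#' read noise. The spot centre is placed on a z slice and jittered by up
#' to half a pixel in x and y.
#'
#' @param copies_per_kinetochore true copy number (>= 0).
#' @param n_kinetochores kinetochores per cluster (16 for the clustered
#'   budding-yeast kinetochores).
#' @param calib a [calibration_standard].
#' @param sd_xy_nm,sd_z_nm rendered spot Gaussian SD (nm).
#' @param pitch_xy,pitch_z voxel pitches (nm).
#' @param dim_px volume size, c(nz, ny, nx).
#' @param background constant offset (camera units).
#' @param gain camera units per photon for the Poisson noise.
#' @param read_sd Gaussian read noise SD (camera units).
#' @param noise add noise? (`FALSE` gives the deterministic expectation).
#' @param seed RNG seed (also drives the sub-pixel jitter).
#' @return list with `volume` (an [image_volume]) and `truth` (class
#'   `ground_truth`: all generator parameters plus the true centre and
#'   amplitude, sufficient to regenerate the volume bit-identically).
#' @export
simulate_cluster_spot <- function(copies_per_kinetochore, n_kinetochores = 16,
                                  calib, sd_xy_nm = 120, sd_z_nm = 300,
                                  pitch_xy = 140, pitch_z = 300,
                                  dim_px = c(7, 15, 15), background = 200,
                                  gain = 2, read_sd = 20, noise = TRUE,
                                  seed = NULL) {
  if (copies_per_kinetochore < 0) stop("copy number must be >= 0")
  stopifnot(inherits(calib, "calibration_standard"))
  if (!is.null(seed)) set.seed(seed)
  nz <- dim_px[1]; ny <- dim_px[2]; nx <- dim_px[3]
  axes <- list(x = (seq_len(nx) - 1) * pitch_xy,
               y = (seq_len(ny) - 1) * pitch_xy,
               z = (seq_len(nz) - 1) * pitch_z)
  center <- c(mean(range(axes$x)) + stats::runif(1, -0.5, 0.5) * pitch_xy,
              mean(range(axes$y)) + stats::runif(1, -0.5, 0.5) * pitch_xy,
              axes$z[(nz + 1) %/% 2])
  amp <- copies_per_kinetochore * n_kinetochores *
    calib$single_gfp_amplitude / calib$power_ratio
  vox <- array(background, dim = c(nz, ny, nx))
  if (amp > 0)
    vox <- add_gaussian_blob(vox, axes, center, amp,
                             c(sd_xy_nm, sd_xy_nm, sd_z_nm))
  if (noise) vox <- apply_camera_noise(vox, gain, read_sd)
  truth <- structure(list(
    copies_per_kinetochore = copies_per_kinetochore,
    n_kinetochores = n_kinetochores,
    single_gfp_amplitude = calib$single_gfp_amplitude,
    power_ratio = calib$power_ratio, amplitude = amp, center_nm = center,
    sd_xy_nm = sd_xy_nm, sd_z_nm = sd_z_nm, background = background,
    gain = gain, read_sd = read_sd, noise = noise, seed = seed),
    class = "ground_truth")
  list(volume = image_volume(vox, pitch_xy, pitch_z, "GFP"), truth = truth)
}

#' Simulate a two-channel SPA-SIM particle population
#'
#' Each particle is a two-channel 3D volume of one mitotic spindle: the
#' mCherry channel holds two SPB fiducial spots (rendered at the measured
#' focal-volume size) separated by a phase-consistent spindle length at a
#' random in-plane orientation; the GFP channel holds one kinetochore
#' cluster per pole, rendered as an anisotropic Gaussian of the requested
#' axial extent (FWHM along the spindle axis) and radial width, centred
#' `cluster_offset` nm from each fiducial toward the spindle midzone.
#'
#' @param n_images number of particles (>= 1).
#' @param phase `"metaphase"` (spindle < 2 um; lengths U(1600, 1950) nm)
#'   or `"anaphase"` (> 2 um; lengths U(2400, 3400) nm).
#' @param axial_extent_fwhm true cluster extent along the spindle axis
#'   (FWHM, nm); defaults to 468.2 (metaphase) or 194.0 (anaphase), the
#'   wild-type Nuf2 values the pipeline is expected to recover.
#' @param radial_fwhm cluster FWHM across the axis and in z (nm).
#' @param cluster_offset fiducial-to-cluster-centre distance (nm).
#' @param spindle_length_range optional c(min, max) override (nm).
#' @param rotation fixed in-plane spindle angle (radians), or `NULL` for
#'   a random angle per image.
#' @param psf [psf_model] used to render the fiducial spots.
#' @param fiducial_amp,cluster_amp peak amplitudes (camera units).
#' @param background,gain,read_sd camera model, as in
#'   [simulate_cluster_spot].
#' @param pitch_xy,pitch_z voxel pitches (nm); defaults are
#'   SIM-reconstruction-like (40 nm xy, 125 nm z).
#' @param nz number of z slices.
#' @param noise add camera noise?
#' @param seed RNG seed.
#' @return list with `particles` (list of lists with [image_volume]s
#'   `gfp` and `mcherry`) and `truth` (generator parameters plus a
#'   per-image data.frame of angles, spindle lengths and fiducial/cluster
#'   centres in nm).
#' @export
simulate_particle_population <- function(n_images = 24,
                                         phase = c("metaphase", "anaphase"),
                                         axial_extent_fwhm = NULL,
                                         radial_fwhm = 250,
                                         cluster_offset = 250,
                                         spindle_length_range = NULL,
                                         rotation = NULL,
                                         psf = psf_model(),
                                         fiducial_amp = 3000,
                                         cluster_amp = 1000,
                                         background = 50, gain = 1,
                                         read_sd = 10, pitch_xy = 40,
                                         pitch_z = 125, nz = 11,
                                         noise = TRUE, seed = NULL) {
  phase <- match.arg(phase)
  if (n_images < 1) stop("n_images must be >= 1")
  if (is.null(axial_extent_fwhm))
    axial_extent_fwhm <- if (phase == "metaphase") 468.2 else 194.0
  if (is.null(spindle_length_range))
    spindle_length_range <- if (phase == "metaphase") c(1600, 1950)
                            else c(2400, 3400)
  if (!is.null(seed)) set.seed(seed)
  margin <- 700                     # nm beyond the fiducials, so a
                                    # +/-600 nm realigned sub-image fits
  half_nm <- spindle_length_range[2] / 2 + margin
  hpx <- ceiling(half_nm / pitch_xy)
  nx <- ny <- 2L * hpx + 1L
  axes <- list(x = (seq_len(nx) - 1) * pitch_xy,
               y = (seq_len(ny) - 1) * pitch_xy,
               z = (seq_len(nz) - 1) * pitch_z)
  cx <- axes$x[hpx + 1L]; cy <- axes$y[hpx + 1L]
  cz <- axes$z[(nz + 1) %/% 2]
  s_ax <- fwhm_to_sigma(axial_extent_fwhm)
  s_rad <- fwhm_to_sigma(radial_fwhm)
  rows <- vector("list", n_images)
  particles <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    th <- if (is.null(rotation)) stats::runif(1, 0, 2 * pi) else rotation
    L <- stats::runif(1, spindle_length_range[1], spindle_length_range[2])
    u <- c(cos(th), sin(th))
    mother <- c(cx - L / 2 * u[1], cy - L / 2 * u[2], cz)
    daughter <- c(cx + L / 2 * u[1], cy + L / 2 * u[2], cz)
    cl_m <- mother + c(cluster_offset * u, 0)
    cl_d <- daughter - c(cluster_offset * u, 0)
    red <- array(background, dim = c(nz, ny, nx))
    red <- add_gaussian_blob(red, axes, mother, fiducial_amp,
                             c(psf$sigma_lateral, psf$sigma_lateral,
                               psf$sigma_axial))
    red <- add_gaussian_blob(red, axes, daughter, fiducial_amp,
                             c(psf$sigma_lateral, psf$sigma_lateral,
                               psf$sigma_axial))
    grn <- array(background, dim = c(nz, ny, nx))
    grn <- add_gaussian_blob(grn, axes, cl_m, cluster_amp,
                             c(s_ax, s_rad, s_rad), theta = th)
    grn <- add_gaussian_blob(grn, axes, cl_d, cluster_amp,
                             c(s_ax, s_rad, s_rad), theta = th)
    if (noise) {
      grn <- apply_camera_noise(grn, gain, read_sd)
      red <- apply_camera_noise(red, gain, read_sd)
    }
    particles[[i]] <- list(
      gfp = image_volume(grn, pitch_xy, pitch_z, "GFP"),
      mcherry = image_volume(red, pitch_xy, pitch_z, "mCherry"))
    rows[[i]] <- data.frame(
      image = i, angle_rad = th, spindle_length_nm = L,
      mother_x = mother[1], mother_y = mother[2], mother_z = mother[3],
      daughter_x = daughter[1], daughter_y = daughter[2],
      daughter_z = daughter[3],
      cluster_m_x = cl_m[1], cluster_m_y = cl_m[2],
      cluster_d_x = cl_d[1], cluster_d_y = cl_d[2])
  }
  truth <- structure(list(
    phase = phase, axial_extent_fwhm = axial_extent_fwhm,
    radial_fwhm = radial_fwhm, cluster_offset = cluster_offset,
    spindle_length_range = spindle_length_range,
    fiducial_amp = fiducial_amp, cluster_amp = cluster_amp,
    background = background, gain = gain, read_sd = read_sd,
    pitch_xy = pitch_xy, pitch_z = pitch_z, noise = noise, seed = seed,
    images = do.call(rbind, rows)), class = "ground_truth")
  list(particles = particles, truth = truth)
}
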