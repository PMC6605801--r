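#' @keywords internal
"_PACKAGE"

# Gaussian FWHM <-> SD conversion factor, 2 sqrt(2 ln 2).
FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

#' Convert between Gaussian FWHM and standard deviation
#'
#' The conversion factor is 2*sqrt(2*ln 2) ~ 2.3548.
#'
#' @param fwhm,sigma lengths (nm).
#' @return the converted length (nm).
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_PER_SIGMA

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) sigma * FWHM_PER_SIGMA

#' Gaussian point-spread-function model
#'
#' Describes the microscope focal volume as an anisotropic 3D Gaussian,
#' parameterized by its lateral (x, y) and axial (z) full widths at half
#' maximum. The defaults are the focal-volume dimensions measured from
#' SPB fiducial reconstructions on a structured-illumination microscope:
#' 119 nm lateral, 272 nm axial.
#'
#' @param fwhm_lateral lateral FWHM (nm), > 0.
#' @param fwhm_axial axial FWHM (nm), > 0.
#' @return An object of class `psf_model` with fields `fwhm_lateral`,
#'   `fwhm_axial`, `sigma_lateral`, `sigma_axial`.
#' @export
psf_model <- function(fwhm_lateral = 119, fwhm_axial = 272) {
  if (fwhm_lateral <= 0 || fwhm_axial <= 0) stop("FWHM values must be > 0")
  structure(list(fwhm_lateral = fwhm_lateral, fwhm_axial = fwhm_axial,
                 sigma_lateral = fwhm_to_sigma(fwhm_lateral),
                 sigma_axial = fwhm_to_sigma(fwhm_axial)),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("psf_model: FWHM %.1f nm lateral / %.1f nm axial (sigma %.1f / %.1f nm)\n",
              x$fwhm_lateral, x$fwhm_axial, x$sigma_lateral, x$sigma_axial))
  invisible(x)
}

# Discrete 1D Gaussian kernel sampled at voxel centres over +/- 4 sigma,
# normalized to unit sum.
gaussian_kernel_1d <- function(sigma_nm, pitch_nm, half_sigmas = 4) {
  half <- ceiling(half_sigmas * sigma_nm / pitch_nm)
  x <- (-half:half) * pitch_nm
  k <- exp(-x^2 / (2 * sigma_nm^2))
  k / sum(k)
}

#' Render a PSF kernel on a voxel grid
#'
#' Samples the 3D Gaussian focal volume on a grid covering +/- 4 sigma in
#' every axis and normalizes it to unit total intensity, so convolution
#' with the kernel conserves integrated signal. The grid must sample the
#' Gaussian adequately (pitch at most FWHM/2 per axis).
#'
#' @param psf a [psf_model].
#' @param pitch_xy lateral grid pitch (nm).
#' @param pitch_z axial grid pitch (nm); defaults to `pitch_xy`.
#' @return An [image_volume] holding the normalized kernel.
#' @export
render_psf <- function(psf, pitch_xy, pitch_z = pitch_xy) {
  stopifnot(inherits(psf, "psf_model"))
  if (pitch_xy > psf$fwhm_lateral / 2)
    stop("undersampled pitch: pitch_xy must be <= lateral FWHM / 2")
  if (pitch_z > psf$fwhm_axial / 2)
    stop("undersampled pitch: pitch_z must be <= axial FWHM / 2")
  kx <- gaussian_kernel_1d(psf$sigma_lateral, pitch_xy)
  ky <- kx
  kz <- gaussian_kernel_1d(psf$sigma_axial, pitch_z)
  vox <- outer(kz, outer(ky, kx))        # dims (nz, ny, nx)
  image_volume(vox, pitch_xy = pitch_xy, pitch_z = pitch_z, channel = "PSF")
}

#' Measure the FWHM of a sampled 1D profile
#'
#' Locates the half-maximum crossings on either side of the peak by linear
#' interpolation and returns their distance. The profile baseline is taken
#' as its minimum.
#'
#' @param position_nm positions (nm), strictly increasing.
#' @param intensity intensities at those positions.
#' @return FWHM in nm, or `NA` if no two crossings exist.
#' @export
measure_fwhm <- function(position_nm, intensity) {
  if (length(position_nm) != length(intensity) || length(intensity) < 3)
    return(NA_real_)
  base <- min(intensity)
  half <- base + (max(intensity) - base) / 2
  ip <- which.max(intensity)
  cross <- function(i0, i1) {
    # linear interpolation of the half-max crossing between samples i0, i1
    y0 <- intensity[i0]; y1 <- intensity[i1]
    position_nm[i0] + (half - y0) / (y1 - y0) *
      (position_nm[i1] - position_nm[i0])
  }
  left <- NA_real_; right <- NA_real_
  for (i in seq(ip, 2)) {
    if (intensity[i - 1] <= half && intensity[i] >= half) {
      left <- cross(i - 1, i); break
    }
  }
  for (i in seq(ip, length(intensity) - 1)) {
    if (intensity[i + 1] <= half && intensity[i] >= half) {
      right <- cross(i + 1, i); break
    }
  }
  right - left
}

# --- separable FFT convolution ---------------------------------------------

# Convolve the columns of a matrix with a centered 1D kernel,
# zero-padded, returning the 'same'-size result.
conv1_fft <- function(mat, k) {
  n <- nrow(mat); lk <- length(k); half <- (lk - 1L) %/% 2L
  nfft <- stats::nextn(n + lk - 1L, 2)
  kf <- stats::fft(c(k, rep(0, nfft - lk)))
  m <- rbind(mat, matrix(0, nfft - n, ncol(mat)))
  out <- Re(stats::mvfft(stats::mvfft(m) * kf, inverse = TRUE)) / nfft
  out[(half + 1L):(half + n), , drop = FALSE]
}

# Convolve a 3D array along one axis with a 1D kernel.
conv_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  out <- conv1_fft(m, k)
  aperm(array(out, dim(ap)), order(perm))
}

#' Convolve a volume with a Gaussian PSF
#'
#' Separable convolution with the discrete kernel of [render_psf] at the
#' volume's own pitches: axial kernel along z, lateral kernel along y and
#' x. Because the kernel has unit sum, total intensity is conserved for
#' sources at least 4 sigma away from the volume borders.
#'
#' @param vol an [image_volume].
#' @param psf a [psf_model].
#' @return the convolved [image_volume].
#' @export
convolve_psf <- function(vol, psf) {
  stopifnot(inherits(vol, "image_volume"), inherits(psf, "psf_model"))
  kl <- gaussian_kernel_1d(psf$sigma_lateral, vol$pitch_xy)
  ka <- gaussian_kernel_1d(psf$sigma_axial, vol$pitch_z)
  v <- conv_axis(vol$voxels, ka, 1L)
  v <- conv_axis(v, kl, 2L)
  v <- conv_axis(v, kl, 3L)
  v[v < 0] <- 0      # clip FFT ringing at the numerical noise floor
  out <- vol
  out$voxels <- v
  out
}
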