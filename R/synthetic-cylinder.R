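#' Geometry of the cylindrical kinetochore forward model
#'
#' Describes kinetochores arranged on the surface of a cylinder coaxial
#' with the spindle: `n_rings` circular rings lying in planes
#' perpendicular to the spindle (y) axis, spaced `ring_spacing` apart,
#' all of the given diameter, rendered on an isotropic grid and imaged by
#' convolution with a Gaussian focal volume. Defaults reproduce the
#' simulation geometry used to interpret bi-lobed metaphase profiles:
#' four rings, 75-nm spacing, 250-nm diameter, 5-nm grid, 119/272-nm PSF.
#'
#' @param n_rings number of rings (>= 1).
#' @param ring_spacing centre-to-centre ring spacing along y (nm).
#' @param diameter ring diameter (nm, >= 0; 0 collapses each ring to an
#'   on-axis point source).
#' @param grid_pitch isotropic rendering pitch (nm, > 0).
#' @param psf a [psf_model] for the focal volume.
#' @param fin1_blob optional extra single 3D Gaussian added to the image
#'   (an SPB-proximal pool such as Fin1): list with `position` (x, y, z nm
#'   relative to the pattern centre), `amplitude`, and `sigma` (scalar or
#'   length-3 nm).
#' @return An object of class `cylinder_spec`.
#' @export
cylinder_spec <- function(n_rings = 4, ring_spacing = 75, diameter = 250,
                          grid_pitch = 5, psf = psf_model(),
                          fin1_blob = NULL) {
  if (n_rings < 1) stop("n_rings must be >= 1")
  if (diameter < 0) stop("diameter must be >= 0")
  if (grid_pitch <= 0) stop("grid_pitch must be > 0")
  stopifnot(inherits(psf, "psf_model"))
  structure(list(n_rings = as.integer(n_rings), ring_spacing = ring_spacing,
                 diameter = diameter, grid_pitch = grid_pitch, psf = psf,
                 fin1_blob = fin1_blob),
            class = "cylinder_spec")
}

# y positions (nm, centred on 0) of the ring planes.
ring_y_positions <- function(spec) {
  (seq_len(spec$n_rings) - (spec$n_rings + 1) / 2) * spec$ring_spacing
}

# Rasterize the rings as voxel-snapped point sources on the cylinder
# surface: one unit-intensity source per distinct voxel on each circle
# (kinetochores sit on the surface, so a 1-voxel annulus, not a disk).
# Returns data.frame(x, y, z) of source coordinates in nm (centred on 0).
cylinder_sources <- function(spec) {
  p <- spec$grid_pitch
  yc <- ring_y_positions(spec)
  r <- spec$diameter / 2
  if (r < p / 2) {
    return(data.frame(x = 0, y = yc, z = 0))
  }
  n_ang <- max(32L, 4L * ceiling(2 * pi * r / p))
  th <- seq(0, 2 * pi, length.out = n_ang + 1L)[-1L]
  ix <- round(r * cos(th) / p)
  iz <- round(r * sin(th) / p)
  keep <- !duplicated(cbind(ix, iz))
  ring <- data.frame(x = ix[keep] * p, z = iz[keep] * p)
  do.call(rbind, lapply(yc, function(y0)
    data.frame(x = ring$x, y = y0, z = ring$z)))
}

#' Simulate imaging of a cylindrical kinetochore arrangement
#'
#' Renders the ring sources of a [cylinder_spec] on an isotropic grid,
#' convolves the volume with the rendered PSF, and optionally adds a
#' single 3D Gaussian blob. The volume is auto-sized to contain the rings
#' plus 4 PSF sigma of margin in every axis; an explicit `extent` smaller
#' than that is rejected.
#'
#' @param spec a [cylinder_spec].
#' @param extent optional c(x, y, z) half-extents (nm) overriding the
#'   automatic volume size.
#' @return An [image_volume] (isotropic pitch `grid_pitch`) with
#'   attributes `center_nm` (x, y, z of the pattern centre) and `spec`.
#' @export
simulate_cylinder_image <- function(spec, extent = NULL) {
  stopifnot(inherits(spec, "cylinder_spec"))
  p <- spec$grid_pitch
  r <- spec$diameter / 2
  sl <- spec$psf$sigma_lateral; sa <- spec$psf$sigma_axial
  need <- c(x = r + 4 * sl, y = max(abs(ring_y_positions(spec))) + 4 * sl,
            z = r + 4 * sa)
  if (is.null(extent)) {
    extent <- need
  } else if (any(extent < need - 1e-9)) {
    stop("volume too small: rings plus 4 PSF sigma do not fit")
  }
  half <- ceiling(extent / p)                # voxels per half-axis (x, y, z)
  nx <- 2L * half[["x"]] + 1L
  ny <- 2L * half[["y"]] + 1L
  nz <- 2L * half[["z"]] + 1L
  vox <- array(0, dim = c(nz, ny, nx))
  src <- cylinder_sources(spec)
  iz <- round(src$z / p) + half[["z"]] + 1L
  iy <- round(src$y / p) + half[["y"]] + 1L
  ix <- round(src$x / p) + half[["x"]] + 1L
  for (i in seq_len(nrow(src)))
    vox[iz[i], iy[i], ix[i]] <- vox[iz[i], iy[i], ix[i]] + 1
  vol <- image_volume(vox, pitch_xy = p, pitch_z = p, channel = "model")
  vol <- convolve_psf(vol, spec$psf)
  if (!is.null(spec$fin1_blob)) {
    b <- spec$fin1_blob
    s <- rep(b$sigma, length.out = 3)        # (x, y, z) sigmas
    ax <- list(x = ((seq_len(nx) - 1) - half[["x"]]) * p,
               y = ((seq_len(ny) - 1) - half[["y"]]) * p,
               z = ((seq_len(nz) - 1) - half[["z"]]) * p)
    gx <- exp(-(ax$x - b$position[1])^2 / (2 * s[1]^2))
    gy <- exp(-(ax$y - b$position[2])^2 / (2 * s[2]^2))
    gz <- exp(-(ax$z - b$position[3])^2 / (2 * s[3]^2))
    vol$voxels <- vol$voxels + b$amplitude * outer(gz, outer(gy, gx))
  }
  attr(vol, "center_nm") <- c(x = half[["x"]] * p, y = half[["y"]] * p,
                              z = half[["z"]] * p)
  attr(vol, "spec") <- spec
  vol
}
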