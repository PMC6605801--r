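#' 3D image volume with physical voxel pitch
#'
#' Container for a single-channel 3D intensity grid. Voxels are stored as a
#' numeric array indexed `[z, y, x]`; positions are voxel-centered, 0-based
#' and reported in nanometres, with y the spindle axis by convention.
#'
#' @param voxels numeric 3D array, dimensions `(nz, ny, nx)`, all finite
#'   and non-negative.
#' @param pitch_xy lateral voxel pitch (nm / pixel), > 0.
#' @param pitch_z axial voxel pitch (nm / slice), > 0.
#' @param channel channel label, e.g. `"GFP"` or `"mCherry"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, pitch_xy = 140, pitch_z = 300,
                         channel = "GFP") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array indexed (z, y, x)")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(voxels))) stop("all intensities must be finite")
  if (any(voxels < 0)) stop("all intensities must be >= 0")
  if (!is.numeric(pitch_xy) || pitch_xy <= 0 || pitch_z <= 0)
    stop("pitch values must be > 0")
  structure(list(voxels = voxels, pitch_xy = pitch_xy, pitch_z = pitch_z,
                 channel = as.character(channel)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "image_volume [%s]: %d x %d x %d voxels (z,y,x), %.0f nm/px xy, %.0f nm/slice z\n",
    x$channel, d[1], d[2], d[3], x$pitch_xy, x$pitch_z))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' Physical axis coordinates of a volume
#'
#' Voxel-center coordinates in nm along each axis (0-based: first voxel
#' at 0).
#'
#' @param vol an [image_volume].
#' @return list with numeric vectors `x`, `y`, `z` (nm).
#' @export
volume_axes <- function(vol) {
  d <- dim(vol$voxels)
  list(x = (seq_len(d[3]) - 1) * vol$pitch_xy,
       y = (seq_len(d[2]) - 1) * vol$pitch_xy,
       z = (seq_len(d[1]) - 1) * vol$pitch_z)
}

#' Extract a 1D intensity profile along one axis
#'
#' Pulls the intensity line parallel to `axis` passing through the voxel
#' closest to the requested physical position in the two other axes.
#'
#' @param vol an [image_volume].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param at named list/vector giving the physical positions (nm) of the
#'   fixed axes; missing entries default to the volume centre.
#' @return data.frame with `position_nm` and `intensity`.
#' @export
profile_along <- function(vol, axis = c("x", "y", "z"), at = NULL) {
  axis <- match.arg(axis)
  d <- dim(vol$voxels)
  ax <- volume_axes(vol)
  idx <- lapply(c(z = 1L, y = 2L, x = 3L), function(i) (d[i] + 1L) %/% 2L)
  for (nm in names(at)) {
    i <- c(z = 1L, y = 2L, x = 3L)[[nm]]
    idx[[nm]] <- which.min(abs(ax[[nm]] - at[[nm]]))
  }
  v <- switch(axis,
              x = vol$voxels[idx$z, idx$y, ],
              y = vol$voxels[idx$z, , idx$x],
              z = vol$voxels[, idx$y, idx$x])
  data.frame(position_nm = ax[[axis]], intensity = as.numeric(v))
}

# --- internal resampling helpers -------------------------------------------

# Bilinear sample of a matrix mat[y, x] at continuous 1-based pixel
# coordinates (ys, xs). Points outside the grid return NA.
bilinear_sample <- function(mat, ys, xs) {
  ny <- nrow(mat); nx <- ncol(mat)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0;   fx <- xs - x0
  out <- rep(NA_real_, length(ys))
  ok <- y0 >= 1 & x0 >= 1 & y0 <= ny & x0 <= nx &
    (y0 + ceiling(fy)) <= ny & (x0 + ceiling(fx)) <= nx
  if (!any(ok)) return(out)
  y0 <- y0[ok]; x0 <- x0[ok]; fy <- fy[ok]; fx <- fx[ok]
  y1 <- pmin(y0 + 1L, ny); x1 <- pmin(x0 + 1L, nx)
  v00 <- mat[cbind(y0, x0)]; v01 <- mat[cbind(y0, x1)]
  v10 <- mat[cbind(y1, x0)]; v11 <- mat[cbind(y1, x1)]
  out[ok] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out
}

# Bilinear upscale of a matrix by an integer factor. Output pixel centres
# map linearly onto the source grid ((i - 0.5)/f + 0.5), edges clamped.
bilinear_upscale <- function(mat, factor) {
  stopifnot(factor >= 1)
  if (factor == 1) return(mat)
  ny <- nrow(mat); nx <- ncol(mat)
  ys <- pmin(pmax((seq_len(ny * factor) - 0.5) / factor + 0.5, 1), ny)
  xs <- pmin(pmax((seq_len(nx * factor) - 0.5) / factor + 0.5, 1), nx)
  g <- expand.grid(y = ys, x = xs)
  matrix(bilinear_sample(mat, g$y, g$x), nrow = ny * factor)
}

# Coordinates (source pixel units) of upscaled pixel centres.
upscale_axis <- function(n, factor) {
  pmin(pmax((seq_len(n * factor) - 0.5) / factor + 0.5, 1), n)
}

# Physical coordinates of upscaled pixel centres, unclamped so the axis
# stays strictly increasing.
upscale_coords <- function(v, factor) {
  n <- length(v)
  step <- (v[n] - v[1]) / (n - 1)
  v[1] + ((seq_len(n * factor) - 0.5) / factor - 0.5) * step
}
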