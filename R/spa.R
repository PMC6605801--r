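# Single-particle averaging of SIM images: fiducial fitting, axis
# realignment, mother/daughter splitting, and averaging.

#' Fit the SPB fiducial pair of one spindle
#'
#' Simultaneous least-squares fit of two 3D Gaussian components (shared
#' lateral and axial SDs, common offset) to the fiducial channel, started
#' from the hand-annotated mother and daughter positions. Only voxels
#' within `crop_nm` (laterally) of either guess enter the fit. The fitted
#' centres define the spindle axis and the spindle length.
#'
#' @param vol fiducial-channel [image_volume].
#' @param init_mother,init_daughter c(x, y, z) initial guesses (nm).
#' @param crop_nm lateral half-width of the fitting region around each
#'   guess.
#' @return An object of class `fiducial_pair` with `mother`, `daughter`
#'   (named x/y/z nm), `spindle_length_nm`, `sigma_xy`, `sigma_z`,
#'   `converged`.
#' @export
fit_fiducial_pair <- function(vol, init_mother, init_daughter,
                              crop_nm = 500) {
  stopifnot(inherits(vol, "image_volume"))
  ax <- volume_axes(vol)
  d <- dim(vol$voxels)
  near <- function(v, c0) abs(v - c0) <= crop_nm
  selx <- near(ax$x, init_mother[1]) | near(ax$x, init_daughter[1])
  sely <- near(ax$y, init_mother[2]) | near(ax$y, init_daughter[2])
  xs <- ax$x[selx]; ys <- ax$y[sely]
  sub <- vol$voxels[, sely, selx, drop = FALSE]
  nzs <- dim(sub)[1]
  Z <- rep(ax$z, times = length(ys) * length(xs))
  Y <- rep(rep(ys, each = nzs), times = length(xs))
  X <- rep(xs, each = nzs * length(ys))
  I <- as.numeric(sub)
  off0 <- stats::median(I)
  amp0 <- max(I) - off0
  init <- c(a1 = amp0, x1 = init_mother[1], y1 = init_mother[2],
            z1 = init_mother[3],
            a2 = amp0, x2 = init_daughter[1], y2 = init_daughter[2],
            z2 = init_daughter[3],
            sxy = 2 * vol$pitch_xy, sz = max(vol$pitch_z, 2 * vol$pitch_xy),
            off = off0)
  resid_fn <- function(p) {
    g1 <- p[["a1"]] * exp(-((X - p[["x1"]])^2 + (Y - p[["y1"]])^2) /
                            (2 * p[["sxy"]]^2) -
                            (Z - p[["z1"]])^2 / (2 * p[["sz"]]^2))
    g2 <- p[["a2"]] * exp(-((X - p[["x2"]])^2 + (Y - p[["y2"]])^2) /
                            (2 * p[["sxy"]]^2) -
                            (Z - p[["z2"]])^2 / (2 * p[["sz"]]^2))
    p[["off"]] + g1 + g2 - I
  }
  lower <- c(a1 = 0, x1 = min(ax$x), y1 = min(ax$y), z1 = min(ax$z),
             a2 = 0, x2 = min(ax$x), y2 = min(ax$y), z2 = min(ax$z),
             sxy = 0.25 * vol$pitch_xy, sz = 0.25 * vol$pitch_z, off = -Inf)
  upper <- c(a1 = Inf, x1 = max(ax$x), y1 = max(ax$y), z1 = max(ax$z),
             a2 = Inf, x2 = max(ax$x), y2 = max(ax$y), z2 = max(ax$z),
             sxy = 20 * vol$pitch_xy, sz = 20 * vol$pitch_z, off = Inf)
  fit <- minpack.lm::nls.lm(par = init, fn = resid_fn, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300))
  p <- stats::setNames(as.numeric(fit$par), names(init))
  mother <- c(x = p[["x1"]], y = p[["y1"]], z = p[["z1"]])
  daughter <- c(x = p[["x2"]], y = p[["y2"]], z = p[["z2"]])
  len <- sqrt(sum((mother - daughter)^2))
  if (!fit$info %in% 1:4)
    stop("fiducial pair fit did not converge")
  if (len < vol$pitch_xy)
    stop("fiducial components merged (centre distance below one pixel)")
  structure(list(mother = mother, daughter = daughter,
                 spindle_length_nm = len, sigma_xy = p[["sxy"]],
                 sigma_z = p[["sz"]], converged = TRUE),
            class = "fiducial_pair")
}

#' @export
print.fiducial_pair <- function(x, ...) {
  cat(sprintf("fiducial_pair: spindle length %.0f nm\n",
              x$spindle_length_nm))
  invisible(x)
}

#' Classify cell-cycle phase from the spindle length
#'
#' Metaphase when the inter-SPB distance is below 2 um, anaphase above;
#' a tie at exactly the threshold is assigned to metaphase.
#'
#' @param pair a [fiducial_pair] (or a spindle length in nm).
#' @param threshold_um phase threshold (micrometres).
#' @return `"metaphase"` or `"anaphase"`.
#' @export
classify_phase <- function(pair, threshold_um = 2) {
  len <- if (inherits(pair, "fiducial_pair")) pair$spindle_length_nm
         else as.numeric(pair)
  ifelse(len <= threshold_um * 1000, "metaphase", "anaphase")
}

#' Realign a particle on its spindle axis and split at the midpoint
#'
#' Rigid in-plane rotation plus translation (bilinear interpolation,
#' slice by slice) placing the inter-fiducial axis on y with the fiducial
#' centres on the x centre line, then division into a mother and a
#' daughter sub-image, each re-centred on its own fiducial along y. The
#' daughter sub-image is flipped vertically so that in every sub-image
#' the fiducial sits at the centre with the spindle pointing toward the
#' image bottom (+y). Sample points falling outside the source volume are
#' zero-filled and counted; a sub-image with more than 10% unfilled
#' pixels is rejected.
#'
#' @param vol an [image_volume] (any channel).
#' @param pair the [fiducial_pair] of this particle.
#' @param half_width_nm sub-image half-width in x (nm).
#' @param half_height_nm sub-image half-height in y (nm).
#' @param max_clipped maximum tolerated unfilled-pixel fraction.
#' @return list of two objects of class `aligned_particle` (`mother`,
#'   `daughter`), each with fields `vol`, `side`, `flipped`,
#'   `fiducial_index` (z, y, x voxel of the fiducial), `ys_nm` / `xs_nm`
#'   (coordinates relative to the fiducial, +y toward the spindle), and
#'   `clipped_fraction`.
#' @export
realign_particle <- function(vol, pair, half_width_nm = 600,
                             half_height_nm = 600, max_clipped = 0.1) {
  stopifnot(inherits(vol, "image_volume"), inherits(pair, "fiducial_pair"))
  p <- vol$pitch_xy
  axis <- pair$daughter[c("x", "y")] - pair$mother[c("x", "y")]
  phi <- atan2(axis[2], axis[1])
  # rotation mapping the axis direction onto +y; inverse maps aligned
  # frame offsets back into source coordinates
  ct <- cos(phi); st <- sin(phi)
  xo <- seq(-half_width_nm, half_width_nm, by = p)
  yo <- seq(-half_height_nm, half_height_nm, by = p)
  nz <- dim(vol$voxels)[1]
  ax <- volume_axes(vol)
  one_side <- function(fid, side, flip) {
    # aligned offset (xo, yo); for flipped sides sample at (xo, -yo)
    ys_eff <- if (flip) -yo else yo
    XO <- matrix(xo, nrow = length(yo), ncol = length(xo), byrow = TRUE)
    YO <- matrix(ys_eff, nrow = length(yo), ncol = length(xo))
    src_x <- fid[["x"]] + st * XO + ct * YO
    src_y <- fid[["y"]] - ct * XO + st * YO
    # continuous 1-based pixel coordinates in the source grid
    px <- src_x / p + 1
    py <- src_y / p + 1
    out <- array(0, dim = c(nz, length(yo), length(xo)))
    miss <- 0L
    for (iz in seq_len(nz)) {
      v <- bilinear_sample(vol$voxels[iz, , ], as.numeric(py),
                           as.numeric(px))
      miss <- miss + sum(is.na(v))
      v[is.na(v)] <- 0
      out[iz, , ] <- v
    }
    frac <- miss / (nz * length(yo) * length(xo))
    if (frac > max_clipped)
      stop(sprintf("more than %.0f%% of the realigned %s sub-image falls outside the source volume",
                   100 * max_clipped, side))
    structure(list(
      vol = image_volume(out, pitch_xy = p, pitch_z = vol$pitch_z,
                         channel = vol$channel),
      side = side, flipped = flip,
      fiducial_index = c(z = which.min(abs(ax$z - fid[["z"]])),
                         y = (length(yo) + 1L) %/% 2L,
                         x = (length(xo) + 1L) %/% 2L),
      ys_nm = yo, xs_nm = xo, clipped_fraction = frac),
      class = "aligned_particle")
  }
  list(mother = one_side(pair$mother, "mother", flip = FALSE),
       daughter = one_side(pair$daughter, "daughter", flip = TRUE))
}

#' Average aligned particles into a single-particle-average image
#'
#' Each aligned particle is maximum-projected over five z slices centred
#' on its fiducial, optionally normalized to its own maximum, and the
#' projections (mother and daughter sub-images pooled) are averaged
#' pixel-wise. The average is upscaled eightfold with bilinear
#' interpolation and averaged with its own left-right mirror image, since
#' no left-right asymmetry is expected for the structures investigated.
#'
#' @param particles list of `aligned_particle` objects with identical
#'   geometry (mother and daughter sides may be pooled freely).
#' @param proj_slices number of z slices in the maximum projection.
#' @param upscale integer upscale factor (bilinear).
#' @param normalize divide each projection by its own maximum before
#'   averaging.
#' @param mirror average with the left-right mirror image.
#' @param phase optional phase label carried through to the result.
#' @return An object of class `spa_image` with fields `img` (matrix,
#'   rows = y), `ys_nm`/`xs_nm` (upscaled pixel centres relative to the
#'   fiducial), `pitch_nm`, `n_images`, `upscale`, `mirrored`, `phase`.
#' @export
average_particles <- function(particles, proj_slices = 5, upscale = 8,
                              normalize = TRUE, mirror = TRUE,
                              phase = NA_character_) {
  stopifnot(length(particles) >= 1)
  keep <- vapply(particles, function(pp) pp$clipped_fraction <= 0.1,
                 logical(1))
  particles <- particles[keep]
  if (!length(particles)) stop("no particles left after clipping filter")
  dims <- vapply(particles, function(pp) dim(pp$vol$voxels)[2:3],
                 integer(2))
  if (any(dims != dims[, 1])) stop("sub-image shape mismatch")
  half <- (proj_slices - 1L) %/% 2L
  projs <- lapply(particles, function(pp) {
    nz <- dim(pp$vol$voxels)[1]
    zr <- max(1L, pp$fiducial_index[["z"]] - half):
      min(nz, pp$fiducial_index[["z"]] + half)
    m <- apply(pp$vol$voxels[zr, , , drop = FALSE], c(2, 3), max)
    if (normalize) m / max(m) else m
  })
  avg <- Reduce(`+`, projs) / length(projs)
  img <- bilinear_upscale(avg, upscale)
  if (mirror) img <- (img + img[, rev(seq_len(ncol(img)))]) / 2
  p0 <- particles[[1]]
  pitch <- p0$vol$pitch_xy
  ys <- (upscale_coords(seq_len(nrow(avg)), upscale) -
           p0$fiducial_index[["y"]]) * pitch
  xs <- (upscale_coords(seq_len(ncol(avg)), upscale) -
           p0$fiducial_index[["x"]]) * pitch
  structure(list(img = img, ys_nm = ys, xs_nm = xs,
                 pitch_nm = pitch / upscale, n_images = length(projs),
                 upscale = as.integer(upscale), mirrored = mirror,
                 phase = phase),
            class = "spa_image")
}

#' @export
print.spa_image <- function(x, ...) {
  cat(sprintf(
    "spa_image: %d x %d px (%.1f nm/px), %d images%s%s\n",
    nrow(x$img), ncol(x$img), x$pitch_nm, x$n_images,
    if (x$mirrored) ", mirror-averaged" else "",
    if (is.na(x$phase)) "" else paste0(", ", x$phase)))
  invisible(x)
}

#' Run the SPA-SIM pipeline on an annotated particle population
#'
#' For every two-channel particle: fit the fiducial pair from the
#' annotated mother/daughter positions, drop pairs whose fitted lateral
#' SD fails the declustering size cutoff, realign the signal channel on
#' the spindle axis, split into mother/daughter sub-images, and average
#' everything into one [spa_image].
#'
#' @param particles list of two-channel particles (each a list with the
#'   signal and fiducial [image_volume]s), e.g. from
#'   [simulate_particle_population].
#' @param annotations data.frame with one row per particle and columns
#'   `mother_x`, `mother_y`, `mother_z`, `daughter_x`, `daughter_y`,
#'   `daughter_z` (nm): the hand-picked initial guesses.
#' @param signal_channel,fiducial_channel names of the channels inside
#'   each particle.
#' @param phase restrict to `"metaphase"` or `"anaphase"` (classified
#'   from the fitted spindle length), or `"both"`.
#' @param sd_max declustering cutoff (nm) applied to the fitted fiducial
#'   lateral SD.
#' @param half_width_nm,half_height_nm sub-image half-sizes, see
#'   [realign_particle].
#' @param proj_slices,upscale,normalize,mirror averaging parameters, see
#'   [average_particles].
#' @return list with `spa` (the [spa_image]), `pairs` (fitted
#'   [fit_fiducial_pair] results) and `included` (logical per particle).
#' @export
spa_average_population <- function(particles, annotations,
                                   signal_channel = "gfp",
                                   fiducial_channel = "mcherry",
                                   phase = c("both", "metaphase",
                                             "anaphase"),
                                   sd_max = 245, half_width_nm = 600,
                                   half_height_nm = 600, proj_slices = 5,
                                   upscale = 8, normalize = TRUE,
                                   mirror = TRUE) {
  phase <- match.arg(phase)
  stopifnot(length(particles) == nrow(annotations))
  pairs <- vector("list", length(particles))
  included <- logical(length(particles))
  aligned <- list()
  for (i in seq_along(particles)) {
    an <- annotations[i, ]
    pair <- tryCatch(
      fit_fiducial_pair(particles[[i]][[fiducial_channel]],
                        c(an$mother_x, an$mother_y, an$mother_z),
                        c(an$daughter_x, an$daughter_y, an$daughter_z)),
      error = function(e) NULL)
    pairs[[i]] <- pair
    if (is.null(pair)) next
    if (pair$sigma_xy >= sd_max) next     # not diffraction-limited
    if (phase != "both" && classify_phase(pair) != phase) next
    al <- tryCatch(
      realign_particle(particles[[i]][[signal_channel]], pair,
                       half_width_nm = half_width_nm,
                       half_height_nm = half_height_nm),
      error = function(e) NULL)
    if (is.null(al)) next
    included[i] <- TRUE
    aligned <- c(aligned, al)
  }
  if (!length(aligned)) stop("no particles passed the filters")
  spa <- average_particles(aligned, proj_slices = proj_slices,
                           upscale = upscale, normalize = normalize,
                           mirror = mirror,
                           phase = if (phase == "both") NA_character_
                                   else phase)
  list(spa = spa, pairs = pairs, included = included)
}
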