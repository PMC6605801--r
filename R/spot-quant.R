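# Gaussian spot fitting and FCS-calibrated copy-number quantification.

#' Fit a 2D Gaussian to a kinetochore spot
#'
#' Following the quantitative-imaging procedure, the z slice with the
#' maximum local intensity near the initial guess is selected and a
#' symmetric 2D Gaussian with constant offset (amplitude, x/y centre,
#' lateral SD, offset) is fitted by Levenberg-Marquardt nonlinear least
#' squares within a window around the guess. The SD is bounded to
#' [0.5, 5] pixels; amplitude is the offset-subtracted peak height.
#'
#' @param vol an [image_volume].
#' @param init numeric c(x, y, z) initial guess (nm) from the annotation
#'   table; must lie inside the volume.
#' @param window_px half-width (pixels) of the xy fitting window.
#' @return An object of class `spot_fit` with fields `center_nm`
#'   (x, y, z), `amplitude`, `sd_nm`, `offset`, `rss`, `converged`.
#' @export
fit_gaussian_spot <- function(vol, init, window_px = 6) {
  stopifnot(inherits(vol, "image_volume"), length(init) >= 2)
  d <- dim(vol$voxels)
  ax <- volume_axes(vol)
  ix <- which.min(abs(ax$x - init[1]))
  iy <- which.min(abs(ax$y - init[2]))
  if (init[1] < min(ax$x) - vol$pitch_xy || init[1] > max(ax$x) + vol$pitch_xy ||
      init[2] < min(ax$y) - vol$pitch_xy || init[2] > max(ax$y) + vol$pitch_xy)
    stop("initial guess outside image bounds")
  xr <- max(1, ix - window_px):min(d[3], ix + window_px)
  yr <- max(1, iy - window_px):min(d[2], iy + window_px)
  # maximum-intensity slice within the local window
  local_max <- vapply(seq_len(d[1]),
                      function(iz) max(vol$voxels[iz, yr, xr]), 0)
  iz <- which.max(local_max)
  sl <- vol$voxels[iz, yr, xr]
  xs <- ax$x[xr]; ys <- ax$y[yr]
  p <- vol$pitch_xy
  off0 <- stats::median(sl)
  init_par <- c(amplitude = max(sl) - off0, x0 = init[1], y0 = init[2],
                sd = p, offset = off0)
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  resid_fn <- function(pp) {
    m <- pp[["offset"]] + pp[["amplitude"]] *
      exp(-((X - pp[["x0"]])^2 + (Y - pp[["y0"]])^2) / (2 * pp[["sd"]]^2))
    as.numeric(m - sl)
  }
  fit <- minpack.lm::nls.lm(
    par = init_par, fn = resid_fn,
    lower = c(amplitude = 0, x0 = min(xs), y0 = min(ys), sd = 0.5 * p,
              offset = -Inf),
    upper = c(amplitude = Inf, x0 = max(xs), y0 = max(ys), sd = 5 * p,
              offset = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  par <- as.numeric(fit$par)
  names(par) <- names(init_par)
  res <- resid_fn(par)
  structure(list(center_nm = c(x = par[["x0"]], y = par[["y0"]],
                               z = ax$z[iz]),
                 amplitude = par[["amplitude"]], sd_nm = par[["sd"]],
                 offset = par[["offset"]], rss = sum(res^2),
                 converged = fit$info %in% 1:4),
            class = "spot_fit")
}

#' @export
print.spot_fit <- function(x, ...) {
  cat(sprintf(
    "spot_fit: amplitude %.1f, sd %.1f nm, centre (%.0f, %.0f, %.0f) nm%s\n",
    x$amplitude, x$sd_nm, x$center_nm[1], x$center_nm[2], x$center_nm[3],
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Filter fitted spots by size to remove declustered kinetochores
#'
#' Keeps exactly the spots whose fitted lateral SD is strictly below
#' `sd_max` (default 245 nm, i.e. 1.75 pixels at 140 nm/pixel), the size
#' cutoff that excludes declustered, non-diffraction-limited spots while
#' not biasing G1 versus anaphase cluster sizes. Order is preserved.
#'
#' @param spots list of [fit_gaussian_spot] results.
#' @param sd_max size cutoff (nm); spots with `sd_nm < sd_max` are kept.
#' @return the filtered list.
#' @export
filter_spots_by_size <- function(spots, sd_max = 245) {
  keep <- vapply(spots, function(s) s$sd_nm < sd_max, logical(1))
  spots[keep]
}

#' Rescale amplitudes acquired at reduced laser power
#'
#' Images of dim samples acquired at reduced power are multiplied by the
#' laser power ratio before comparison with the single-GFP calibration.
#'
#' @param amplitude spot amplitude(s), camera units.
#' @param calib a [calibration_standard] carrying `power_ratio`.
#' @return rescaled amplitude(s).
#' @export
apply_power_scaling <- function(amplitude, calib) {
  stopifnot(inherits(calib, "calibration_standard"))
  amplitude * calib$power_ratio
}

#' GFP copy number from a calibrated spot amplitude
#'
#' Compares the (power-scaled) spot amplitude with the predicted
#' amplitude of a single GFP molecule to obtain the total copy number of
#' the cluster, and divides by the number of kinetochores per cluster
#' (16 for budding yeast: one microtubule per chromosome, 16 chromosomes)
#' for the per-kinetochore count.
#'
#' @param amplitude spot amplitude(s), camera units (offset-subtracted).
#' @param calib a [calibration_standard].
#' @param n_kinetochores kinetochores per cluster.
#' @return list with `copies_total` and `copies_per_kinetochore`.
#' @export
copies_from_amplitude <- function(amplitude, calib, n_kinetochores = 16) {
  stopifnot(inherits(calib, "calibration_standard"))
  if (calib$single_gfp_amplitude <= 0)
    stop("calibration amplitude must be > 0")
  total <- apply_power_scaling(amplitude, calib) / calib$single_gfp_amplitude
  list(copies_total = total,
       copies_per_kinetochore = total / n_kinetochores)
}

#' Normalized intensity in the 0-10 range
#'
#' Reported intensities are Gaussian amplitudes in camera intensity units
#' divided by 1,000 or 10,000 to put them in the 0-10 range.
#'
#' @param amplitude amplitude(s) in camera units.
#' @param divisor 1000 or 10000.
#' @return dimensionless normalized intensity.
#' @export
normalized_intensity <- function(amplitude, divisor = 1000) {
  if (!divisor %in% c(1000, 10000))
    stop("divisor must be 1000 or 10000")
  amplitude / divisor
}

#' Anaphase/G1 intensity ratio with propagated error
#'
#' Ratio of the mean anaphase to mean G1 normalized intensity, with its
#' standard error propagated to first order from the standard errors of
#' the two means: `SE = ratio * sqrt((SE_A/mean_A)^2 + (SE_G/mean_G)^2)`.
#' A two-tailed Welch t test between the groups is attached as a
#' convenience.
#'
#' @param anaphase,g1 numeric vectors of per-cluster normalized
#'   intensities (non-empty).
#' @return An object of class `ratio_estimate` with `ratio`, `se`,
#'   `n_numerator`, `n_denominator`, and `t_test` (htest or NULL).
#' @export
anaphase_g1_ratio <- function(anaphase, g1) {
  if (length(anaphase) < 1 || length(g1) < 1)
    stop("both groups must be non-empty")
  ma <- mean(anaphase); mg <- mean(g1)
  if (mg == 0) stop("zero G1 mean intensity")
  sea <- if (length(anaphase) > 1) stats::sd(anaphase) / sqrt(length(anaphase)) else 0
  seg <- if (length(g1) > 1) stats::sd(g1) / sqrt(length(g1)) else 0
  ratio <- ma / mg
  se <- abs(ratio) * sqrt((sea / ma)^2 + (seg / mg)^2)
  tt <- if (length(anaphase) > 1 && length(g1) > 1 &&
            (stats::sd(anaphase) > 0 || stats::sd(g1) > 0))
    stats::t.test(anaphase, g1) else NULL
  structure(list(ratio = ratio, se = se, n_numerator = length(anaphase),
                 n_denominator = length(g1), t_test = tt),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("anaphase/G1 ratio %.3f +/- %.3f (n = %d / %d)\n",
              x$ratio, x$se, x$n_numerator, x$n_denominator))
  invisible(x)
}

#' Distance between two fitted spot centres
#'
#' Euclidean distance in physical units, e.g. the inter-cluster distance
#' used as a spindle-length proxy.
#'
#' @param spot_a,spot_b converged [fit_gaussian_spot] results.
#' @return distance in nm.
#' @export
cluster_separation <- function(spot_a, spot_b) {
  stopifnot(inherits(spot_a, "spot_fit"), inherits(spot_b, "spot_fit"))
  if (!spot_a$converged || !spot_b$converged)
    stop("both spot fits must have converged")
  sqrt(sum((spot_a$center_nm - spot_b$center_nm)^2))
}
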