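# FRAP normalization and percent-recovery quantification.

#' FRAP intensity time course
#'
#' Holds one bleached-cluster intensity trace with its sampling times and
#' the indices of the prebleach frame and first post-bleach frame.
#'
#' @param times sampling times (minutes), strictly increasing.
#' @param intensity cluster intensity per frame (camera units).
#' @param prebleach_index index of the prebleach frame (default 1).
#' @param postbleach_index index of the first post-bleach frame (default
#'   2); must exceed `prebleach_index`.
#' @return An object of class `frap_curve`.
#' @export
frap_curve <- function(times, intensity, prebleach_index = 1,
                       postbleach_index = 2) {
  if (length(times) != length(intensity))
    stop("times and intensity must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (prebleach_index >= postbleach_index)
    stop("prebleach index must precede the post-bleach index")
  if (postbleach_index > length(times))
    stop("post-bleach index outside the series")
  structure(list(times = times, intensity = intensity,
                 prebleach_index = as.integer(prebleach_index),
                 postbleach_index = as.integer(postbleach_index),
                 normalized = FALSE),
            class = "frap_curve")
}

#' Normalize a FRAP curve to its prebleach intensity
#'
#' Every frame is divided by the prebleach intensity, so the normalized
#' prebleach frame equals 1 exactly.
#'
#' @param curve a [frap_curve] with positive prebleach intensity.
#' @return the normalized [frap_curve].
#' @export
normalize_frap <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"))
  pre <- curve$intensity[curve$prebleach_index]
  if (!is.finite(pre) || pre <= 0)
    stop("prebleach intensity must be > 0")
  curve$intensity <- curve$intensity / pre
  curve$normalized <- TRUE
  curve
}

#' Percent fluorescence recovery after photobleaching
#'
#' `100 * (I_end - I_post) / (I_pre - I_post)` on the normalized curve,
#' with `I_pre = 1`, `I_post` the mean of the first `post_window`
#' post-bleach frames and `I_end` the mean of the final `end_window`
#' frames. Values outside [0, 150] are returned unclamped but flagged.
#'
#' @param curve a [frap_curve]; normalized with [normalize_frap] first if
#'   necessary.
#' @param post_window frames averaged for the post-bleach level.
#' @param end_window frames averaged for the endpoint level.
#' @return list with `percent` and logical `flagged`.
#' @export
percent_recovery <- function(curve, post_window = 1, end_window = 2) {
  stopifnot(inherits(curve, "frap_curve"))
  if (!curve$normalized) curve <- normalize_frap(curve)
  i <- curve$intensity
  n <- length(i)
  p0 <- curve$postbleach_index
  if (p0 > n) stop("no post-bleach frames")
  post <- mean(i[p0:min(n, p0 + post_window - 1)])
  endw <- mean(i[max(p0, n - end_window + 1):n])
  if (post >= 1)
    stop("bleach failed: post-bleach intensity not below prebleach")
  pct <- 100 * (endw - post) / (1 - post)
  list(percent = pct, flagged = pct < 0 || pct > 150)
}

#' Summarize percent recovery across cells and groups
#'
#' Per-group mean and SD of percent recovery, with a two-tailed Welch t
#' test between two groups.
#'
#' @param percents numeric vector of per-cell percent recoveries.
#' @param groups group labels, same length (>= 2 cells per group).
#' @return list with `summary` (data.frame: group, n, mean, sd) and
#'   `t_test` (htest when exactly two groups, else NULL).
#' @export
recovery_summary <- function(percents, groups) {
  if (length(percents) != length(groups))
    stop("percents and groups must have equal length")
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("need >= 2 curves per group")
  sm <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- percents[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  tt <- NULL
  if (nlevels(groups) == 2) {
    a <- percents[groups == levels(groups)[1]]
    b <- percents[groups == levels(groups)[2]]
    tt <- if (stats::sd(a) > 0 || stats::sd(b) > 0)
      stats::t.test(a, b)
    else list(statistic = c(t = 0), p.value = 1)
  }
  list(summary = sm, t_test = tt)
}

#' Correct acquisition photobleaching with an unbleached control trace
#'
#' Optional exponential detrend: a mono-exponential decay is fitted to an
#' unbleached control intensity trace and the curve is divided by the
#' fitted decay (normalized to 1 at the prebleach frame). Off by default
#' in all pipelines; acquisition at long intervals usually keeps
#' acquisition bleaching negligible.
#'
#' @param curve a [frap_curve].
#' @param control control-region intensities, same length as the curve.
#' @return the detrended [frap_curve].
#' @export
bleach_detrend <- function(curve, control) {
  stopifnot(inherits(curve, "frap_curve"),
            length(control) == length(curve$times))
  t <- curve$times - curve$times[curve$prebleach_index]
  c0 <- control[curve$prebleach_index]
  f <- tryCatch({
    fit <- minpack.lm::nls.lm(
      par = c(k = 1e-3),
      fn = function(p) c0 * exp(-p[["k"]] * t) - control,
      lower = c(k = 0))
    exp(-as.numeric(fit$par[["k"]]) * t)
  }, error = function(e) rep(1, length(t)))
  curve$intensity <- curve$intensity / f
  curve
}
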