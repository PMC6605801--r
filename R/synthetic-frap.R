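#' Ground truth for a simulated FRAP time course
#'
#' Parameters of an exponential-recovery bleach experiment: the prebleach
#' intensity, the fraction remaining immediately after the bleach, the
#' plateau fraction approached during recovery, and the recovery time
#' constant. The first sampling time is the prebleach frame; the bleach
#' occurs between the first and second frames.
#'
#' @param prebleach prebleach intensity (camera units, > 0).
#' @param post_frac post-bleach fraction of prebleach, in [0, 1].
#' @param plateau_frac plateau recovery fraction, `post_frac <= plateau
#'   <= 1`.
#' @param tau_min recovery time constant (minutes, > 0).
#' @param times sampling times (minutes), strictly increasing, length
#'   >= 2.
#' @return An object of class `frap_series_truth`.
#' @export
frap_series_truth <- function(prebleach = 1000, post_frac = 0.2,
                              plateau_frac = 0.6, tau_min = 8,
                              times = seq(0, 40, by = 2)) {
  if (prebleach <= 0) stop("prebleach must be > 0")
  if (post_frac < 0 || post_frac > 1) stop("post_frac must be in [0, 1]")
  if (plateau_frac < post_frac || plateau_frac > 1)
    stop("need post_frac <= plateau_frac <= 1")
  if (tau_min <= 0) stop("tau_min must be > 0")
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing, length >= 2")
  structure(list(prebleach = prebleach, post_frac = post_frac,
                 plateau_frac = plateau_frac, tau_min = tau_min,
                 times = times),
            class = "frap_series_truth")
}

#' Simulate a FRAP intensity time course
#'
#' The prebleach frame sits at the prebleach level; from the first
#' post-bleach frame onward the intensity follows
#' `prebleach * (post + (plateau - post) * (1 - exp(-t / tau)))`, with
#' `t` measured from the first post-bleach frame, plus optional Gaussian
#' noise.
#'
#' @param truth a [frap_series_truth].
#' @param noise_sd Gaussian noise SD as a fraction of the prebleach
#'   intensity (0 for a noiseless series).
#' @param seed RNG seed.
#' @return data.frame with `time_min` and `intensity`; the truth is
#'   attached as attribute `"truth"`.
#' @export
simulate_frap_series <- function(truth, noise_sd = 0.02, seed = NULL) {
  stopifnot(inherits(truth, "frap_series_truth"))
  if (!is.null(seed)) set.seed(seed)
  t <- truth$times
  i <- truth$prebleach * rep(1, length(t))
  post <- t[-1] - t[2]                     # recovery clock from first
  i[-1] <- truth$prebleach *               # post-bleach frame
    (truth$post_frac + (truth$plateau_frac - truth$post_frac) *
       (1 - exp(-post / truth$tau_min)))
  if (noise_sd > 0)
    i <- i + stats::rnorm(length(i), 0, noise_sd * truth$prebleach)
  out <- data.frame(time_min = t, intensity = i)
  attr(out, "truth") <- truth
  out
}
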