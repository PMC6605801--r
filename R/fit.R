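# Shared Gaussian least-squares fitting helpers. All nonlinear fits in
# the package go through minpack.lm's Levenberg-Marquardt implementation.

# Fit y ~ offset + amplitude * exp(-(x - center)^2 / (2 sd^2)).
# Returns par (amplitude, center, sd, offset), fitted, residuals, rss,
# converged.
gauss1d_fit <- function(x, y, init = NULL, sd_bounds = NULL) {
  if (is.null(init)) {
    off <- min(y)
    amp <- max(y) - off
    ctr <- x[which.max(y)]
    w <- pmax(y - off, 0)
    sd0 <- sqrt(sum(w * (x - ctr)^2) / max(sum(w), .Machine$double.eps))
    if (!is.finite(sd0) || sd0 <= 0) sd0 <- diff(range(x)) / 6
    init <- c(amplitude = amp, center = ctr, sd = sd0, offset = off)
  }
  if (is.null(sd_bounds))
    sd_bounds <- c(min(diff(x)) / 4, diff(range(x)))
  resid_fn <- function(p) {
    p[["offset"]] + p[["amplitude"]] *
      exp(-(x - p[["center"]])^2 / (2 * p[["sd"]]^2)) - y
  }
  lower <- c(amplitude = 0, center = min(x), sd = sd_bounds[1],
             offset = -Inf)
  upper <- c(amplitude = Inf, center = max(x), sd = sd_bounds[2],
             offset = Inf)
  fit <- minpack.lm::nls.lm(par = init, fn = resid_fn, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  par <- stats::setNames(as.numeric(fit$par), names(init))
  res <- resid_fn(par)
  # resid_fn returns model - y, so model values are y + res and the
  # conventional residuals (y - model) are -res
  list(par = par, fitted = y + res, residuals = -res, rss = sum(res^2),
       converged = fit$info %in% 1:4)
}

#' Monte Carlo standard errors from fit residuals
#'
#' Estimates parameter standard errors of a converged least-squares fit
#' by refitting `n` noisy replicates of the fitted model, with i.i.d.
#' Gaussian noise whose SD equals the SD of the fit residuals (the
#' residual distribution approximated as Gaussian). The SE of each
#' parameter is the SD of its refit values.
#'
#' @param refit function taking a data vector and returning a named
#'   numeric parameter vector (or signalling an error on failure).
#' @param fitted fitted model values at the data points.
#' @param residuals fit residuals (data minus fitted).
#' @param n number of Monte Carlo replicates (default 100).
#' @param seed RNG seed.
#' @param max_fail maximum tolerated refit failure rate.
#' @return named numeric vector of standard errors, with attribute
#'   `"n_ok"` (number of successful refits).
#' @export
mc_parameter_errors <- function(refit, fitted, residuals, n = 100,
                                seed = NULL, max_fail = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  s <- stats::sd(residuals)
  if (!is.finite(s)) s <- 0
  draws <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    y <- fitted + stats::rnorm(length(fitted), 0, s)
    p <- tryCatch(refit(y), error = function(e) NULL)
    if (!is.null(p) && all(is.finite(p))) {
      draws[[i]] <- p; ok[i] <- TRUE
    }
  }
  if (mean(!ok) > max_fail)
    stop(sprintf("Monte Carlo refit failure rate %.0f%% exceeds %.0f%%",
                 100 * mean(!ok), 100 * max_fail))
  m <- do.call(rbind, draws[ok])
  se <- apply(m, 2, stats::sd)
  attr(se, "n_ok") <- sum(ok)
  se
}
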