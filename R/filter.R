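# Bandpass filter model: sum of two first-order lowpass branches with a
# common delay,
#   H(f) = gamma1 e^{-2 pi i f Delta} [ 1/(1 + i f/f_c1) + gamma2/(1 + i f/f_c2) ]
# The characteristic frequencies are bounded via the time constants
# tau_c = 1/(2 pi f_c) in [0.25, 175] ms, the delay Delta in [0, 75] ms.

#' Filter frequency bounds
#'
#' Lower and upper bounds on the characteristic frequencies, derived from the
#' admissible filter time constants 0.25 ms <= tau_c <= 175 ms via
#' `f_c = 1/(2 pi tau_c)`: about 0.909 Hz and 636.6 Hz.
#'
#' @return named vector `c(lower =, upper =)` in Hz.
#' @export
filter_frequency_bounds <- function() {
  c(lower = 1000 / (2 * pi * 175), upper = 1000 / (2 * pi * 0.25))
}

DELTA_MAX <- 75

#' Bandpass filter parameters
#'
#' @param gamma1 linear gain (output s^-1 per input s^-1).
#' @param gamma2 unitless gain of the second (faster) branch.
#' @param f_c1,f_c2 characteristic frequencies in Hz with
#'   `f_c1 <= f_c2`, both within [filter_frequency_bounds()]. Use
#'   [swap_filter_branches()] to normalize a raw fit with `f_c1 > f_c2`.
#' @param delta common delay in ms, within `[0, 75]`.
#' @return object of class `filter_params`; derived time constants
#'   `tau_1 = 1/(2 pi f_c1)` and `tau_2 = 1/(2 pi f_c2)` (ms) are stored.
#' @export
filter_params <- function(gamma1, gamma2, f_c1, f_c2, delta) {
  b <- filter_frequency_bounds()
  tol <- 1e-6
  check_scalar(gamma1, "gamma1")
  check_scalar(gamma2, "gamma2")
  check_scalar(f_c1, "f_c1", lower = b[["lower"]] - tol, upper = b[["upper"]] + tol)
  check_scalar(f_c2, "f_c2", lower = b[["lower"]] - tol, upper = b[["upper"]] + tol)
  check_scalar(delta, "delta", lower = 0, upper = DELTA_MAX + tol)
  if (f_c1 > f_c2 + tol)
    stopf("f_c1 > f_c2; apply swap_filter_branches() first")
  structure(list(gamma1 = gamma1, gamma2 = gamma2,
                 f_c1 = f_c1, f_c2 = f_c2, delta = delta,
                 tau_1 = 1000 / (2 * pi * f_c1),
                 tau_2 = 1000 / (2 * pi * f_c2)),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf(
    "<filter_params> gamma1=%.4g gamma2=%.4g f_c1=%.4g Hz f_c2=%.4g Hz delta=%.4g ms\n",
    x$gamma1, x$gamma2, x$f_c1, x$f_c2, x$delta))
  invisible(x)
}

#' Normalize filter branch order
#'
#' When a raw fit ends with `f_c1 > f_c2`, the two branches are relabelled so
#' that `f_c1` is always the lower characteristic frequency:
#' `(f_c1, f_c2) <- (f_c2, f_c1)` and `(gamma1, gamma2) <- (gamma1 gamma2,
#' 1/gamma2)`, which leaves the filter unchanged.
#'
#' @param gamma1,gamma2,f_c1,f_c2,delta raw parameter values.
#' @return named list of normalized parameters.
#' @export
swap_filter_branches <- function(gamma1, gamma2, f_c1, f_c2, delta) {
  if (f_c1 > f_c2) {
    if (gamma2 == 0) {
      # second branch is inert; relabel its frequency to restore the order
      out <- list(gamma1 = gamma1, gamma2 = 0,
                  f_c1 = f_c1, f_c2 = f_c1, delta = delta)
      return(out)
    }
    out <- list(gamma1 = gamma1 * gamma2, gamma2 = 1 / gamma2,
                f_c1 = f_c2, f_c2 = f_c1, delta = delta)
  } else {
    out <- list(gamma1 = gamma1, gamma2 = gamma2,
                f_c1 = f_c1, f_c2 = f_c2, delta = delta)
  }
  out
}

#' Evaluate the bandpass filter at given frequencies
#'
#' @param p a [filter_params()] (or list with the same fields).
#' @param f frequencies in Hz (`>= 0`).
#' @return complex gains; at `f = 0` exactly `gamma1 (1 + gamma2)`.
#' @export
eval_filter <- function(p, f) {
  if (any(f < 0)) stopf("frequencies must be >= 0")
  p$gamma1 * exp(-2i * pi * f * p$delta / 1000) *
    (1 / (1 + 1i * f / p$f_c1) + p$gamma2 / (1 + 1i * f / p$f_c2))
}

# residual loss of a raw parameter vector against measured points
filter_loss <- function(par, freq, Hobs, amplitude_only = FALSE) {
  # par: gamma1, gamma2, log10 f_c1, log10 f_c2, delta
  Hm <- par[1] * exp(-2i * pi * freq * par[5] / 1000) *
    (1 / (1 + 1i * freq / 10^par[3]) + par[2] / (1 + 1i * freq / 10^par[4]))
  if (amplitude_only) sum((Mod(Hm) - Mod(Hobs))^2) else sum(Mod(Hm - Hobs)^2)
}

lowpass_loss <- function(par, freq, Hobs, amplitude_only = FALSE) {
  # par: gamma1, log10 f_c, delta
  Hm <- par[1] * exp(-2i * pi * freq * par[3] / 1000) / (1 + 1i * freq / 10^par[2])
  if (amplitude_only) sum((Mod(Hm) - Mod(Hobs))^2) else sum(Mod(Hm - Hobs)^2)
}

#' Fit the bandpass filter to an empirical transfer function
#'
#' Minimizes the summed squared modulus of the complex residuals between the
#' filter model and the measured transfer-function points over
#' `(gamma1, gamma2, f_c1, f_c2, delta)`, subject to the frequency bounds
#' (time constants between 0.25 and 175 ms) and `0 <= delta <= 75 ms`. The global
#' search uses bounded local minimization (L-BFGS-B) from `n_starts` random
#' starting points, keeping the best; a pure lowpass filter (`gamma2 = 0`)
#' is fitted for comparison from `n_starts_lowpass` starts and both losses
#' are reported. If the best fit has `f_c1 > f_c2` the branches are swapped
#' (see [swap_filter_branches()]).
#'
#' @param tf a `transfer_function_estimate` (see
#'   [measure_transfer_function()]) or a list/data frame with fields `f`
#'   (Hz), `H` (complex) and optionally `valid`.
#' @param n_starts number of random starts for the bandpass fit.
#' @param n_starts_lowpass number of random starts for the lowpass
#'   comparison.
#' @param seed optional seed making the multi-start search deterministic.
#' @param amplitude_only fit `|H|` only instead of the complex residual
#'   (sensitivity option).
#' @return list with `params` ([filter_params()]), `loss`, `lowpass`
#'   (`params` with `gamma2 = 0`, and `loss`), and `n_points`.
#' @export
fit_filter <- function(tf, n_starts = 60, n_starts_lowpass = 15, seed = NULL,
                       amplitude_only = FALSE) {
  f <- tf$f
  H <- tf$H
  valid <- tf$valid %||% rep(TRUE, length(f))
  keep <- valid & is.finite(f) & is.finite(Re(H)) & is.finite(Im(H))
  f <- f[keep]
  H <- H[keep]
  if (length(f) < 8L)
    stopf("need >= 8 valid transfer-function points, got %d", length(f))
  b <- filter_frequency_bounds()
  lb <- c(-1e4, -1e4, log10(b[["lower"]]), log10(b[["lower"]]), 0)
  ub <- c(1e4, 1e4, log10(b[["upper"]]), log10(b[["upper"]]), DELTA_MAX)
  scale_guess <- stats::median(Mod(H))

  one_start <- function() {
    g2 <- stats::runif(1, -3, 3)
    lf <- sort(stats::runif(2, lb[3], ub[3]))
    dl <- if (stats::runif(1) < 0.8) stats::runif(1, 0, 10) else
      stats::runif(1, 0, DELTA_MAX)
    # closed-form least-squares gain given the shape parameters
    Fsh <- exp(-2i * pi * f * dl / 1000) *
      (1 / (1 + 1i * f / 10^lf[1]) + g2 / (1 + 1i * f / 10^lf[2]))
    g1 <- Re(sum(Conj(Fsh) * H)) / max(sum(Mod(Fsh)^2), 1e-12)
    if (!is.finite(g1) || abs(g1) < 1e-8) g1 <- scale_guess
    p0 <- c(min(max(g1, lb[1]), ub[1]), g2, lf[1], lf[2], dl)
    res <- tryCatch(
      stats::optim(p0, filter_loss, freq = f, Hobs = H,
                   amplitude_only = amplitude_only,
                   method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 400)),
      error = function(e) NULL)
    res
  }
  one_start_lp <- function() {
    lf <- stats::runif(1, lb[3], ub[3])
    dl <- stats::runif(1, 0, 10)
    Fsh <- exp(-2i * pi * f * dl / 1000) / (1 + 1i * f / 10^lf)
    g1 <- Re(sum(Conj(Fsh) * H)) / max(sum(Mod(Fsh)^2), 1e-12)
    if (!is.finite(g1) || abs(g1) < 1e-8) g1 <- scale_guess
    tryCatch(
      stats::optim(c(min(max(g1, lb[1]), ub[1]), lf, dl), lowpass_loss,
                   freq = f, Hobs = H, amplitude_only = amplitude_only,
                   method = "L-BFGS-B",
                   lower = lb[c(1, 3, 5)], upper = ub[c(1, 3, 5)],
                   control = list(maxit = 400)),
      error = function(e) NULL)
  }

  with_seed(seed, {
    lps <- Filter(Negate(is.null),
                  lapply(seq_len(n_starts_lowpass), function(i) one_start_lp()))
    best_lp <- if (length(lps)) lps[[which.min(vapply(lps, `[[`, 0, "value"))]]
               else NULL
    fits <- Filter(Negate(is.null), lapply(seq_len(n_starts), function(i) one_start()))
    if (!is.null(best_lp)) {
      # seed one bandpass start at the lowpass optimum: the bandpass family
      # contains the lowpass (gamma2 = 0), so its loss can never be worse
      from_lp <- tryCatch(
        stats::optim(c(best_lp$par[1], 0, best_lp$par[2],
                       mean(c(lb[4], ub[4])), best_lp$par[3]),
                     filter_loss, freq = f, Hobs = H,
                     amplitude_only = amplitude_only,
                     method = "L-BFGS-B", lower = lb, upper = ub,
                     control = list(maxit = 400)),
        error = function(e) NULL)
      if (!is.null(from_lp)) fits <- c(fits, list(from_lp))
    }
    if (!length(fits)) stopf("all %d fit starts failed", n_starts)
    best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]

    pp <- best$par
    sw <- swap_filter_branches(pp[1], pp[2], 10^pp[3], 10^pp[4], pp[5])
    params <- filter_params(sw$gamma1, sw$gamma2, sw$f_c1, sw$f_c2, sw$delta)
    lp_params <- if (!is.null(best_lp))
      filter_params(best_lp$par[1], 0, 10^best_lp$par[2],
                    10^best_lp$par[2], best_lp$par[3]) else NULL
    list(params = params, loss = best$value,
         lowpass = list(params = lp_params,
                        loss = if (is.null(best_lp)) NA_real_ else best_lp$value),
         n_points = length(f))
  })
}
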