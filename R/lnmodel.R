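#' Linear-nonlinear rate model
#'
#' The deliverable rate model: `r(t) = max(0, g((h * a)(t)))` with the
#' activation function `g` and the causal normalized kernel
#'
#'   `h(t) = Theta(t - Delta) [ e^{-(t-Delta)/tau1}/tau1
#'            + gamma2 e^{-(t-Delta)/tau2}/tau2 ] / (1 + gamma2)`
#'
#' (`tau_k = 1/(2 pi f_ck)`), whose integral is exactly 1, so a stationary
#' input `a0` produces `g(a0)`. The linear gain `gamma1` is fully captured by
#' the activation function and does not enter the prediction.
#'
#' @param activation an [activation_function()].
#' @param filter a [filter_params()]; `|1 + gamma2|` must exceed `1e-12`
#'   (kernel normalization guard).
#' @param provenance optional list recording the condition the model was
#'   fitted under (`a0`, `a1`, `mu`, `sigma`, `w`, ...).
#' @return object of class `ln_model`.
#' @export
ln_model <- function(activation, filter, provenance = list()) {
  stopifnot(inherits(activation, "activation_function"))
  if (!inherits(filter, "filter_params"))
    filter <- do.call(filter_params, filter[c("gamma1", "gamma2", "f_c1",
                                              "f_c2", "delta")])
  if (abs(1 + filter$gamma2) <= 1e-12)
    stopf("kernel normalization undefined: |1 + gamma2| <= 1e-12")
  structure(list(activation = activation, filter = filter,
                 provenance = provenance),
            class = "ln_model")
}

#' @export
print.ln_model <- function(x, ...) {
  cat("<ln_model>\n  ")
  print(x$filter)
  cat("  ")
  print(x$activation)
  invisible(x)
}

# Discretized normalized kernel: exact integrals of h over grid bins, so that
# convolution with a zero-order-hold input reproduces the exact linear
# filter response. The delay is snapped to the grid. Truncated where the
# remaining tail mass is below ~1e-12.
ln_kernel_bins <- function(filter, dt) {
  g2 <- filter$gamma2
  c1 <- 1 / (1 + g2)
  c2 <- g2 / (1 + g2)
  t1 <- filter$tau_1
  t2 <- filter$tau_2
  d_bins <- as.integer(round(filter$delta / dt))
  # tail length: exp(-K) * max(|c1|,|c2|) < 1e-12
  K <- 28 + log(max(abs(c1), abs(c2), 1))
  n_tail <- as.integer(ceiling(K * max(t1, t2) / dt)) + 1L
  k <- seq_len(n_tail) - 1L
  seg <- function(ci, ti) ci * (exp(-k * dt / ti) - exp(-(k + 1) * dt / ti))
  G <- seg(c1, t1) + seg(c2, t2)
  list(G = G, d_bins = d_bins)
}

#' Predict the firing rate by convolution
#'
#' Evaluates `r(t) = max(0, g((h * a)(t)))` on a uniform grid by discrete
#' convolution with the exactly bin-integrated kernel (the delay is snapped
#' to the grid). The rectification only guards against negative rates from
#' extrapolating the activation function.
#'
#' @param m an [ln_model()].
#' @param a input rate trace in s^-1 (`>= 0`) on a uniform grid.
#' @param dt grid step in ms.
#' @param init history before the trace: `"stationary"` pads with `a[1]`
#'   (the system starts at its fixed point for the initial rate), `"zero"`
#'   pads with zeros.
#' @return predicted rate trace in s^-1, same length as `a`; values are
#'   aligned with the end of each input bin.
#' @export
predict_convolution <- function(m, a, dt = 0.1,
                                init = c("stationary", "zero")) {
  stopifnot(inherits(m, "ln_model"))
  init <- match.arg(init)
  if (any(a < 0)) stopf("input rate must be >= 0")
  kb <- ln_kernel_bins(m$filter, dt)
  G <- kb$G
  npad <- length(G) + kb$d_bins
  a_ext <- c(rep(if (init == "stationary") a[1] else 0, npad), a)
  n <- length(a_ext)
  nk <- kb$d_bins + length(G)
  mfft <- stats::nextn(n + nk, 2)
  fa <- stats::fft(c(a_ext, numeric(mfft - n)))
  fg <- stats::fft(c(numeric(kb$d_bins), G, numeric(mfft - nk)))
  u <- Re(stats::fft(fa * fg, inverse = TRUE)) / mfft
  u <- u[npad + seq_along(a)]
  pmax(0, eval_activation(m$activation, u))
}

#' Predict the firing rate by the equivalent ODE system
#'
#' Integrates the linear-chain representation of the kernel,
#' `u1' = -u1/tau1 + a(t - Delta) c1/tau1`, `u2' = -u2/tau2 +
#' a(t - Delta) c2/tau2` with `c1 = 1/(1+gamma2)`, `c2 = gamma2/(1+gamma2)`,
#' by an exact exponential-integrator step per grid bin (the subsystem is
#' linear, so there is no truncation error for piecewise-constant input);
#' the delay is handled by an input buffer. Returns
#' `max(0, g(u1 + u2))`, matching [predict_convolution()] to numerical
#' precision.
#'
#' @inheritParams predict_convolution
#' @return predicted rate trace in s^-1, same length as `a`.
#' @export
predict_ode <- function(m, a, dt = 0.1, init = c("stationary", "zero")) {
  stopifnot(inherits(m, "ln_model"))
  init <- match.arg(init)
  if (any(a < 0)) stopf("input rate must be >= 0")
  g2 <- m$filter$gamma2
  if (abs(1 + g2) <= 1e-12) stopf("kernel normalization undefined")
  c1 <- 1 / (1 + g2)
  c2 <- g2 / (1 + g2)
  t1 <- m$filter$tau_1
  t2 <- m$filter$tau_2
  d_bins <- as.integer(round(m$filter$delta / dt))
  a_hist <- if (init == "stationary") a[1] else 0
  a_del <- c(rep(a_hist, d_bins), a)[seq_along(a)]
  al1 <- exp(-dt / t1)
  al2 <- exp(-dt / t2)
  u10 <- c1 * a_hist
  u20 <- c2 * a_hist
  u1 <- stats::filter(c1 * (1 - al1) * a_del, al1, method = "recursive",
                      init = u10)
  u2 <- stats::filter(c2 * (1 - al2) * a_del, al2, method = "recursive",
                      init = u20)
  u <- as.numeric(u1) + as.numeric(u2)
  pmax(0, eval_activation(m$activation, u))
}
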