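#' Linear-B-spline activation function
#'
#' Container for the stationary input-rate to output-rate mapping
#' `r0 = g(a0)` of a spiking model: measured rates at a knot grid plus a
#' continuous linear interpolant that passes through every knot exactly and
#' extrapolates linearly beyond the measured range.
#'
#' @param a0 knot grid of stationary input rates (s^-1).
#' @param r0 measured stationary output rates (s^-1), one per knot.
#' @param metadata optional list (model, noise regime, weight, ...).
#' @return object of class `activation_function`; evaluate it with
#'   [eval_activation()].
#' @export
activation_function <- function(a0, r0, metadata = list()) {
  if (length(a0) != length(r0) || length(a0) < 2L)
    stopf("need matching a0/r0 vectors with >= 2 knots")
  if (any(diff(a0) <= 0)) stopf("a0 knots must be strictly increasing")
  structure(list(a0 = as.numeric(a0), r0 = as.numeric(r0),
                 metadata = metadata),
            class = "activation_function")
}

#' Evaluate an activation function
#'
#' Linear interpolation between knots; linear extrapolation with the slope of
#' the first/last segment outside the knot range.
#'
#' @param g an [activation_function()].
#' @param x input rates (s^-1).
#' @return output rates (s^-1), possibly negative under extrapolation (the LN
#'   prediction rectifies).
#' @export
eval_activation <- function(g, x) {
  stopifnot(inherits(g, "activation_function"))
  a <- g$a0
  r <- g$r0
  nk <- length(a)
  out <- stats::approx(a, r, xout = x, rule = 2)$y
  lo <- x < a[1]
  hi <- x > a[nk]
  if (any(lo))
    out[lo] <- r[1] + (x[lo] - a[1]) * (r[2] - r[1]) / (a[2] - a[1])
  if (any(hi))
    out[hi] <- r[nk] + (x[hi] - a[nk]) * (r[nk] - r[nk - 1]) / (a[nk] - a[nk - 1])
  out
}

#' @export
print.activation_function <- function(x, ...) {
  md <- x$metadata
  lab <- if (length(md)) paste0(" [", paste(names(md), unlist(md), sep = "=",
                                            collapse = ", "), "]") else ""
  cat(sprintf("<activation_function> %d knots on [%g, %g] s^-1%s\n",
              length(x$a0), min(x$a0), max(x$a0), lab))
  invisible(x)
}

#' Measure the activation function of a spiking model
#'
#' Drives the model with stationary Poisson input (no modulation) plus the
#' given background-noise regime at every rate of the knot grid (default 0 to
#' 1000 s^-1 in steps of 10, i.e. 101 knots), measures the mean output rate
#' after equilibration, and returns the linear-B-spline interpolant.
#'
#' @param spec a [model_spec()].
#' @param noise a [noise_preset()] for the matching class.
#' @param w synaptic weight (fraction of `xi` for Izhikevich, pA for AMAT).
#' @param a0_grid knot grid of stationary input rates in s^-1.
#' @param duration measurement duration per knot in ms (default 10000).
#' @param equilibration equilibration period per knot in ms.
#' @param dt time step in ms.
#' @param seed optional seed.
#' @return an [activation_function()] with measurement metadata.
#' @export
measure_activation_function <- function(spec, noise, w,
                                        a0_grid = seq(0, 1000, by = 10),
                                        duration = 10000, equilibration = 1000,
                                        dt = 0.1, seed = NULL) {
  stopifnot(inherits(spec, "model_spec") || inherits(spec, "rate_surrogate_spec"))
  with_seed(seed, {
    r0 <- vapply(a0_grid, function(a0) {
      tr <- simulate_ensemble(spec, n = 1L, rate = a0, w = w, noise = noise,
                              config = simulation_config(duration, dt,
                                                         equilibration))[[1]]
      train_rate(tr)
    }, 0)
    activation_function(a0_grid, r0,
                        metadata = list(model = spec$label, class = spec$class,
                                        noise = noise$name %||% "custom", w = w))
  })
}

#' Linearity score of a rate curve over an interval
#'
#' Finds the best least-squares line `l(x)` to the curve over `[alpha, beta]`
#' and computes the normalized mean-square deviation
#' `Lbar1 = mean((f - l)^2) / l((alpha+beta)/2)^2`, returned as the bounded
#' score `L1 = 1 / (1 + Lbar1)`. `L1 = 1` indicates a perfectly linear curve;
#' `L1 = 1/2` a deviation equal to the mean value. The evaluation window for
#' a working point `(a0, a1)` is `[a0 - a1, a0 + a1]`.
#'
#' @param g an [activation_function()] or a plain function of one argument.
#' @param alpha,beta interval bounds (`beta > alpha`).
#' @param n_grid quadrature grid size (trapezoidal rule).
#' @return `L1` in (0, 1], or `NA` (flagged with attribute `reason`) when the
#'   best line vanishes at the midpoint and the normalization is undefined.
#' @export
linearity_L1 <- function(g, alpha, beta, n_grid = 4001L) {
  if (beta <= alpha) stopf("need beta > alpha")
  f <- if (inherits(g, "activation_function")) function(x) eval_activation(g, x)
       else match.fun(g)
  x <- seq(alpha, beta, length.out = n_grid)
  fx <- f(x)
  tw <- rep(1, n_grid)
  tw[c(1L, n_grid)] <- 0.5                      # trapezoid weights
  # continuous least-squares line via weighted normal equations
  sw <- sum(tw)
  mx <- sum(tw * x) / sw
  mf <- sum(tw * fx) / sw
  q <- sum(tw * (x - mx) * (fx - mf)) / sum(tw * (x - mx)^2)
  p <- mf - q * mx
  lx <- p + q * x
  lmid <- p + q * (alpha + beta) / 2
  if (abs(lmid) < .Machine$double.eps^0.5) {
    out <- NA_real_
    attr(out, "reason") <- "best line vanishes at interval midpoint"
    return(out)
  }
  lbar <- (sum(tw * (fx - lx)^2) / sw) / lmid^2
  1 / (1 + lbar)
}

#' Classify spikes as isolated or burst spikes
#'
#' A spike belongs to a burst when its distance to the preceding or the
#' following spike is at most `dT` (default 5 ms, the upper limit of
#' intra-burst intervals used for the raster classification).
#'
#' @param train a [spike_train()].
#' @param dT burst criterion in ms.
#' @return character vector of labels `"isolated"` / `"burst"`, one per spike.
#' @export
classify_burst_spikes <- function(train, dT = 5) {
  stopifnot(inherits(train, "spike_train"))
  tm <- train$times
  nt <- length(tm)
  if (!nt) return(character(0))
  isi_prev <- c(Inf, diff(tm))
  isi_next <- c(diff(tm), Inf)
  ifelse(isi_prev <= dT | isi_next <= dT, "burst", "isolated")
}
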