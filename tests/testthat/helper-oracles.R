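# Independent oracles used across the suite. These re-derive expected values
# by direct translation / brute force and must stay independent of the
# package implementation paths they check.

# Direct-translation forward-Euler loop for the Izhikevich dynamics, written
# as a plain R loop with the same arithmetic ordering as the documented
# update rule.
izh_euler_oracle <- function(prm, v0, u0, current, jumps, dt, n_steps,
                             substeps = 1L) {
  v <- v0
  u <- u0
  spikes <- integer(0)
  h <- dt / substeps
  for (n in seq_len(n_steps)) {
    I <- prm$i_ext
    if (length(current)) I <- I + current[n]
    if (length(jumps)) v <- v + jumps[n]
    for (s in seq_len(substeps))
      v <- v + h * (0.04 * v * v + 5.0 * v + 140.0 - u + I)
    u <- u + dt * (prm$a * (prm$b * v - u))
    if (v >= prm$v_th) {
      spikes <- c(spikes, n)
      v <- prm$c
      u <- u + prm$d
    }
  }
  list(spikes = spikes, v = v, u = u)
}

# Closed-form postsynaptic-potential deviation (mV) of a first-order membrane
# (tau_m, C_m) driven by an exponential synaptic current of weight w (pA)
# arriving at time t0; evaluated at times t (ms).
amat_psp_oracle <- function(t, t0, w, tau_m = 10, tau_s = 1, c_m = 200) {
  dt <- t - t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- (w / c_m) * (exp(-dt[pos] / tau_s) - exp(-dt[pos] / tau_m)) /
    (1 / tau_m - 1 / tau_s)
  out
}

# Fine-grid Euler integration of the AMAT subthreshold membrane for the
# single-spike PSP peak (per pA), independent of the propagator code.
amat_psp_peak_numeric <- function(tau_m = 10, tau_s = 1, c_m = 200,
                                  dt = 0.001, t_max = 30) {
  n <- round(t_max / dt)
  v <- 0
  i_syn <- 1
  peak <- 0
  for (k in seq_len(n)) {
    v <- v + dt * (-v / tau_m + i_syn / c_m)
    i_syn <- i_syn - dt * i_syn / tau_s
    if (v > peak) peak <- v
  }
  peak
}

# Brute-force fixed-kernel KDE cost on binned spike times (double loop over
# the binned count vector).
kde_cost_oracle <- function(times, t0, bin_width, widths) {
  b <- floor((times - t0) / bin_width)
  n <- length(times)
  ks <- function(w) {
    s <- 0
    for (i in seq_len(n)) s <- s + sum(stats::dnorm((b - b[i]) * bin_width,
                                                    sd = w))
    s
  }
  vapply(widths, function(w) {
    ks(w * sqrt(2)) - 2 * (ks(w) - n * stats::dnorm(0, sd = w))
  }, 0)
}

# O(n^2) burst labelling.
burst_oracle <- function(times, dT = 5) {
  n <- length(times)
  lab <- character(n)
  for (i in seq_len(n)) {
    near <- FALSE
    for (j in seq_len(n)) {
      if (j != i && abs(times[j] - times[i]) <= dT) near <- TRUE
    }
    lab[i] <- if (near) "burst" else "isolated"
  }
  lab
}

# Bernoulli-dialect inhomogeneous Poisson train written independently of the
# package generator (plain R, one runif per bin).
poisson_train_oracle <- function(rate_bins, dt, t_start = 0) {
  p <- rate_bins * dt / 1000
  hit <- which(stats::runif(length(p)) < p)
  spike_train((hit - 1) * dt + t_start, t_start = t_start,
              t_stop = t_start + length(p) * dt)
}

# Linear LN surrogate: spiking responder whose rate is the LN model's own
# prediction of the input rate profile.
make_ln_surrogate <- function(m) {
  rate_surrogate_spec(function(rb, dt)
    predict_convolution(m, rb, dt = dt, init = "stationary"),
    label = "ln-surrogate")
}
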