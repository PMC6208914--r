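#' Sinusoidal rate specification
#'
#' Rate profile `a(t) = a0 + a1 sin(2 pi f_stim t)` of a sinusoidally
#' modulated inhomogeneous Poisson process. The modulation depth is limited
#' to `0 <= a1 <= a0` to avoid rectification.
#'
#' @param a0 mean rate in s^-1.
#' @param a1 modulation depth in s^-1.
#' @param f_stim modulation frequency in Hz.
#' @return object of class `sinusoidal_rate`; callable as a function of time
#'   via [rate_at()].
#' @export
sinusoidal_rate <- function(a0, a1, f_stim) {
  check_scalar(a0, "a0", lower = 0)
  check_scalar(a1, "a1", lower = 0)
  check_scalar(f_stim, "f_stim", lower = .Machine$double.eps)
  if (a1 > a0) stopf("modulation depth a1 = %g exceeds a0 = %g", a1, a0)
  structure(list(a0 = a0, a1 = a1, f_stim = f_stim), class = "sinusoidal_rate")
}

#' Evaluate a rate specification at given times
#' @param rate a `sinusoidal_rate` or `rate_schedule`.
#' @param t times in ms.
#' @return rate values in s^-1.
#' @export
rate_at <- function(rate, t) UseMethod("rate_at")

#' @export
rate_at.sinusoidal_rate <- function(rate, t) {
  rate$a0 + rate$a1 * sin(2 * pi * rate$f_stim * t / 1000)
}

#' @export
rate_at.rate_schedule <- function(rate, t) {
  idx <- findInterval(t, c(rate$t_start, rate$t_end[nrow(rate)]),
                      rightmost.closed = FALSE)
  idx[idx < 1 | idx > nrow(rate)] <- NA
  out <- rate$rate[idx]
  out[is.na(out)] <- 0
  out
}

#' Piecewise-constant rate schedule
#'
#' Contiguous, non-overlapping intervals with constant rates; rates change
#' instantaneously at interval boundaries.
#'
#' @param t_start,t_end interval boundaries in ms; intervals must tile
#'   `[t_start[1], t_end[n])` exactly.
#' @param rate rates in s^-1, one per interval, all `>= 0`.
#' @return object of class `rate_schedule` (a data frame).
#' @export
rate_schedule <- function(t_start, t_end, rate) {
  if (!(length(t_start) == length(t_end) && length(t_end) == length(rate)))
    stopf("t_start, t_end, rate must have equal length")
  if (any(rate < 0)) stopf("rates must be >= 0")
  if (any(t_end <= t_start)) stopf("empty or inverted interval")
  if (length(t_start) > 1 && any(abs(t_start[-1] - t_end[-length(t_end)]) > 1e-9))
    stopf("intervals must be contiguous and non-overlapping")
  structure(data.frame(t_start = t_start, t_end = t_end, rate = rate),
            class = c("rate_schedule", "data.frame"))
}

#' Default stepped-Poisson test schedule
#'
#' The four-interval profile used as test stimulus: 100 s^-1 for 0-600 ms,
#' 200 s^-1 for 600-1000 ms, 40 s^-1 for 1000-1200 ms and 150 s^-1 for
#' 1200-1500 ms.
#'
#' @return a [rate_schedule()].
#' @export
default_rate_schedule <- function() {
  rate_schedule(t_start = c(0, 600, 1000, 1200),
                t_end = c(600, 1000, 1200, 1500),
                rate = c(100, 200, 40, 150))
}

# Per-bin rates (s^-1) for a schedule on a dt grid over [0, T_total)
schedule_bins <- function(schedule, dt, n) {
  rate_at(schedule, (seq_len(n) - 0.5) * dt)
}

#' Generate a sinusoidally modulated Poisson spike train
#'
#' One Bernoulli draw per `dt` bin with `p = a(t) dt`, evaluated at bin
#' centres (the grid-based generator dialect); the exact time-rescaling
#' alternative is available via `method = "rescaling"` for cross-checks.
#'
#' @param rate a [sinusoidal_rate()].
#' @param T duration in ms.
#' @param dt bin width in ms.
#' @param seed optional seed.
#' @param method `"bernoulli"` (grid dialect, default) or `"rescaling"`
#'   (exact inversion of the cumulative intensity).
#' @return a [spike_train()] on `[0, T)`; Bernoulli spikes are stamped at bin
#'   starts.
#' @export
sinusoidal_poisson_train <- function(rate, T, dt = 0.1, seed = NULL,
                                     method = c("bernoulli", "rescaling")) {
  stopifnot(inherits(rate, "sinusoidal_rate"))
  method <- match.arg(method)
  n <- as.integer(round(T / dt))
  if (n < 1) stopf("empty or negative duration")
  if (method == "bernoulli") {
    p <- rate_to_p(function(t) rate_at(rate, t), dt, n)
    with_seed(seed, {
      bins <- bernoulli_bins(p)
      spike_train(bins * dt, t_start = 0, t_stop = T)
    })
  } else {
    # time rescaling: invert Lambda(t) = a0 t + (a1 / 2 pi f)(1 - cos(2 pi f t))
    with_seed(seed, {
      lam <- function(t) rate$a0 * t / 1000 +
        rate$a1 / (2 * pi * rate$f_stim) *
          (1 - cos(2 * pi * rate$f_stim * t / 1000))
      n_exp <- stats::rpois(1, lam(T))
      # draw unit-rate event positions and invert numerically
      u <- sort(stats::runif(n_exp, 0, lam(T)))
      times <- vapply(u, function(ui)
        stats::uniroot(function(t) lam(t) - ui, c(0, T), tol = 1e-9)$root, 0)
      times <- times[times < T]
      times <- times[!duplicated(times)]
      spike_train(sort(times), t_start = 0, t_stop = T)
    })
  }
}

#' Generate a piecewise-constant-rate Poisson spike train
#'
#' @param schedule a [rate_schedule()]; the default is the stepped test
#'   profile of [default_rate_schedule()].
#' @param dt bin width in ms.
#' @param seed optional seed.
#' @return a [spike_train()] over the schedule's span.
#' @export
piecewise_poisson_train <- function(schedule = default_rate_schedule(),
                                    dt = 0.1, seed = NULL) {
  stopifnot(inherits(schedule, "rate_schedule"))
  T <- schedule$t_end[nrow(schedule)] - schedule$t_start[1]
  n <- as.integer(round(T / dt))
  off <- schedule$t_start[1]
  p <- rate_to_p(rate_at(schedule, off + (seq_len(n) - 0.5) * dt), dt, n)
  with_seed(seed, {
    bins <- bernoulli_bins(p)
    spike_train(off + bins * dt, t_start = off, t_stop = off + T)
  })
}

#' Solve for background Poisson event rates from target current statistics
#'
#' Background noise for the AMAT class is injected as excitatory and
#' inhibitory Poisson event trains through exponential current synapses.
#' The resulting shot-noise current has mean
#' `mu = w_E nu_E tau_E + w_I nu_I tau_I` and variance
#' `sigma^2 = w_E^2 nu_E tau_E / 2 + w_I^2 nu_I tau_I / 2`
#' (time constants in seconds). This function inverts the two equations for
#' the event rates `nu_E`, `nu_I`.
#'
#' @param mu_bg,sigma_bg target mean and standard deviation of the noise
#'   current in pA.
#' @param w_e,w_i synaptic weights in pA (defaults 1 and -4/3).
#' @param tau_e,tau_i synaptic time constants in ms (defaults 1 and 3).
#' @return named vector `c(nu_e =, nu_i =)` in s^-1.
#' @export
solve_background_rates <- function(mu_bg, sigma_bg, w_e = 1, w_i = -4 / 3,
                                   tau_e = 1, tau_i = 3) {
  check_scalar(sigma_bg, "sigma_bg", lower = 0)
  te <- tau_e / 1000
  ti <- tau_i / 1000
  # linear 2x2 system in (nu_e, nu_i)
  A <- rbind(c(w_e * te, w_i * ti),
             c(w_e^2 * te / 2, w_i^2 * ti / 2))
  sol <- solve(A, c(mu_bg, sigma_bg^2))
  if (any(sol < -1e-9))
    stopf("no non-negative rate solution: nu = (%.4g, %.4g)", sol[1], sol[2])
  c(nu_e = max(sol[1], 0), nu_i = max(sol[2], 0))
}

# preset transient times (ms) of the packaged synthetic RGC-like profile:
# 12 irregularly spaced events per 8 s
rgc_event_times_default <- c(310, 905, 1480, 2120, 2700, 3330,
                             4060, 4660, 5290, 5980, 6700, 7430)

#' Generate synthetic retinal-ganglion-cell-like spike trains
#'
#' Inhomogeneous Poisson trains emulating the summary statistics of the
#' retinal-ganglion-cell recordings used as realistic test input: low
#' baseline firing with sharp transients, 96 trains of 8 s each and a
#' grand-mean single-train rate of about 18.3 s^-1. The rate profile is a
#' constant baseline plus Gaussian bumps at the event times; with the
#' packaged defaults the bump amplitude is calibrated so the expected mean
#' rate equals 18.3 s^-1.
#'
#' @param n_trains number of trains (default 96).
#' @param T train duration in ms (default 8000).
#' @param baseline_rate baseline rate in s^-1 (default 8).
#' @param event_times transient centres in ms (default: packaged preset of 12
#'   events).
#' @param event_amplitude transient peak amplitude in s^-1; `NULL` (default)
#'   calibrates it so the expected grand-mean rate is `target_rate`.
#' @param event_width Gaussian standard deviation of a transient in ms
#'   (default 15).
#' @param target_rate expected grand-mean single-train rate in s^-1 used for
#'   calibration when `event_amplitude` is `NULL`.
#' @param dt bin width in ms.
#' @param seed optional seed.
#' @return list of `n_trains` [spike_train()] objects on `[0, T)`.
#' @export
synth_rgc_trains <- function(n_trains = 96, T = 8000, baseline_rate = 8,
                             event_times = rgc_event_times_default,
                             event_amplitude = NULL, event_width = 15,
                             target_rate = 18.3, dt = 0.1, seed = NULL) {
  check_scalar(n_trains, "n_trains", lower = 1)
  check_scalar(T, "T", lower = dt)
  check_scalar(baseline_rate, "baseline_rate", lower = 0)
  check_scalar(event_width, "event_width", lower = .Machine$double.eps)
  if (is.null(event_amplitude)) {
    if (target_rate < baseline_rate)
      stopf("target_rate below baseline_rate; cannot calibrate")
    # bump integral (spikes per bump) needed to lift the mean to target_rate
    per_bump <- (target_rate - baseline_rate) * (T / 1000) / length(event_times)
    event_amplitude <- per_bump / (event_width / 1000 * sqrt(2 * pi))
  }
  check_scalar(event_amplitude, "event_amplitude", lower = 0)
  n <- as.integer(round(T / dt))
  tt <- (seq_len(n) - 0.5) * dt
  r <- rep(baseline_rate, n)
  for (te in event_times)
    r <- r + event_amplitude * exp(-((tt - te)^2) / (2 * event_width^2))
  p <- rate_to_p(r, dt, n)
  with_seed(seed, lapply(seq_len(n_trains), function(i) {
    spike_train(bernoulli_bins(p) * dt, t_start = 0, t_stop = T)
  }))
}

#' Merge spike trains pairwise
#'
#' Train `i` of the output is the sorted union of input trains `2i - 1` and
#' `2i`; the total spike count is conserved. Used to double the mean rate of
#' the synthetic RGC-like set (96 trains at ~18.3 s^-1 become 48 trains at
#' ~36.6 s^-1).
#'
#' @param trains list of an even number of [spike_train()] objects on a
#'   common time window.
#' @return list of `length(trains)/2` merged trains.
#' @export
merge_train_pairs <- function(trains) {
  if (length(trains) %% 2L != 0L)
    stopf("need an even number of trains, got %d", length(trains))
  lapply(seq_len(length(trains) / 2L), function(i) {
    a <- trains[[2L * i - 1L]]
    b <- trains[[2L * i]]
    if (abs(a$t_start - b$t_start) > 1e-9 || abs(a$t_stop - b$t_stop) > 1e-9)
      stopf("trains %d and %d have different time windows", 2L * i - 1L, 2L * i)
    tm <- sort(c(a$times, b$times))
    # coincident spikes on the grid are kept distinct by a half-bin offset
    dup <- which(diff(tm) <= 0)
    while (length(dup)) {
      tm[dup + 1L] <- tm[dup] + 1e-6
      tm <- sort(tm)
      dup <- which(diff(tm) <= 0)
    }
    spike_train(tm, t_start = a$t_start, t_stop = a$t_stop)
  })
}
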