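#' Simulation configuration
#'
#' All simulations run on a fixed time grid of width `dt` (default 0.1 ms).
#' The total simulated time is `equilibration + T`; output spikes are recorded
#' only during the recording window `[equilibration, equilibration + T)`,
#' while the state (and any stimulus) evolves from time 0.
#'
#' @param T recording duration in ms.
#' @param dt time step in ms.
#' @param equilibration equilibration period in ms before recording starts.
#' @param seed optional integer seed; when given, the simulation is run in a
#'   temporary RNG stream and is fully reproducible.
#' @param record_voltage record the state trace (membrane potential and, for
#'   the AMAT class, the instantaneous threshold).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(T, dt = 0.1, equilibration = 1000, seed = NULL,
                              record_voltage = FALSE) {
  check_scalar(T, "T", lower = .Machine$double.eps)
  check_scalar(dt, "dt", lower = .Machine$double.eps)
  check_scalar(equilibration, "equilibration", lower = 0)
  structure(list(T = T, dt = dt, equilibration = equilibration, seed = seed,
                 record_voltage = isTRUE(record_voltage)),
            class = "simulation_config")
}

n_steps_total <- function(config) {
  as.integer(round((config$T + config$equilibration) / config$dt))
}

# Snap input spikes (time ms, weight) to the grid: times are floored to the
# grid, multiple spikes in one step sum their weights. Returns a per-step
# weight vector of length n (zeros where no spike).
spikes_to_bins <- function(input_spikes, dt, n) {
  if (is.null(input_spikes) || NROW(input_spikes) == 0L) return(numeric(0))
  if (is.list(input_spikes) && !is.data.frame(input_spikes))
    input_spikes <- data.frame(time = input_spikes$time,
                               weight = input_spikes$weight)
  tm <- as.numeric(input_spikes[[1]])
  wt <- as.numeric(input_spikes[[2]])
  # floored to the grid; the small tolerance keeps intended grid multiples
  # (e.g. 4.9/0.1 = 48.999...) in their own bin
  bin <- floor(tm / dt + 1e-6) + 1
  if (any(bin < 1 | bin > n)) stopf("input spike time outside the simulation window")
  out <- numeric(n)
  agg <- rowsum(wt, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Per-bin Bernoulli probabilities from a rate specification (scalar s^-1,
# function of time in ms, or per-bin vector), evaluated at bin centres.
rate_to_p <- function(rate, dt, n) {
  if (is.null(rate)) return(numeric(0))
  r <- if (is.function(rate)) {
    rate((seq_len(n) - 0.5) * dt)
  } else if (length(rate) == 1L) {
    rep(as.numeric(rate), n)
  } else {
    if (length(rate) != n) stopf("rate vector must have %d bins", n)
    as.numeric(rate)
  }
  if (any(r < 0)) stopf("negative rate in stimulus profile")
  p <- r * dt / 1000
  if (any(p > 1)) stopf("rate too high for the grid: a(t)*dt > 1")
  p
}

#' Simulate an Izhikevich model neuron
#'
#' Forward-Euler integration of the canonical two-variable dynamics
#' `v' = 0.04 v^2 + 5 v + 140 - u + I`, `u' = a (b v - u)` with reset
#' `v <- c`, `u <- u + d` at `v >= v_th`. Input spikes add their weight to
#' `v` instantaneously (weights are supplied already multiplied out, i.e. as
#' fractions of `xi` times `xi`). All quantities except time (ms) and `v`
#' (mV) are treated as unitless.
#'
#' @param params an `izhikevich_params` object.
#' @param input_spikes optional data frame (time ms, weight); times are floored
#'   to the grid and colliding spikes sum their weights.
#' @param poisson_input optional `list(rate =, w =)` stimulus: an inhomogeneous
#'   Poisson train generated in the integration loop by one Bernoulli draw per
#'   bin with `p = a(t) dt`, each spike adding `w` to `v`. `rate` may be a
#'   scalar (s^-1), a function of time (ms) or a per-bin vector.
#' @param current optional injected-current vector, one value per step.
#' @param noise `NULL`, a per-step noise-current trace (e.g. from
#'   [gaussian_noise_current()]), a `list(mu =, sigma =)` drawn freshly every
#'   step inside the loop, or a `noise_preset`.
#' @param config a [simulation_config()].
#' @param state optional carried-over state `list(v =, u =)` from a previous
#'   run; when absent, `v(0) ~ U(-70, 30)` and `u(0) = b v(0)`.
#' @param substeps number of membrane-potential substeps per `dt` (the
#'   recovery variable is updated once per step); the default 1 integrates on
#'   the plain 0.1 ms grid.
#' @return list with `spikes` (a [spike_train()] over the recording window,
#'   absolute times), `state` (final `v`, `u`), and `trace` (data frame
#'   `time_ms`, `v_mV`, `u` when `record_voltage` is set).
#' @export
simulate_izhikevich <- function(params, input_spikes = NULL,
                                poisson_input = NULL, current = NULL,
                                noise = NULL, config, state = NULL,
                                substeps = 1L) {
  stopifnot(inherits(params, "izhikevich_params"),
            inherits(config, "simulation_config"))
  n <- n_steps_total(config)
  dt <- config$dt
  jump <- spikes_to_bins(input_spikes, dt, n)
  p <- if (is.null(poisson_input)) numeric(0) else
    rate_to_p(poisson_input$rate, dt, n)
  w_jump <- if (is.null(poisson_input)) 0 else as.numeric(poisson_input$w)
  if (!is.null(current) && length(current) != n)
    stopf("current trace must have %d steps", n)
  if (inherits(noise, "noise_preset")) noise <- list(mu = noise$mu, sigma = noise$sigma)
  noise_trace <- NULL
  mu <- sg <- 0
  use_noise <- FALSE
  if (is.numeric(noise)) {
    if (length(noise) != n) stopf("noise trace must have %d steps", n)
    noise_trace <- noise
  } else if (is.list(noise)) {
    mu <- noise$mu
    sg <- noise$sigma
    use_noise <- (mu != 0 || sg != 0)
  }
  cur <- if (is.null(current) && is.null(noise_trace)) numeric(0) else
    (if (is.null(current)) 0 else current) +
    (if (is.null(noise_trace)) 0 else noise_trace)

  with_seed(config$seed, {
    if (is.null(state)) {
      v0 <- stats::runif(1, -70, 30)
      u0 <- params$b * v0
    } else {
      v0 <- state$v
      u0 <- state$u
    }
    res <- izhikevich_kernel(params$a, params$b, params$c, params$d,
                             params$v_th, params$i_ext,
                             cur, jump, p, w_jump, mu, sg, use_noise,
                             v0, u0, dt, n, as.integer(substeps),
                             config$record_voltage)
    finish_sim(res, config, trace_cols = c(v_mV = "v_trace", u = "u_trace"),
               state = list(v = res$v, u = res$u))
  })
}

finish_sim <- function(res, config, trace_cols, state) {
  dt <- config$dt
  # a spike emitted during step n is stamped at the step's start time, so
  # all spike times lie on the grid inside [0, T_total)
  times <- (res$spike_steps - 1L) * dt
  t0 <- config$equilibration
  t1 <- config$equilibration + config$T
  times <- times[times >= t0 & times < t1]
  trace <- NULL
  if (config$record_voltage) {
    trace <- data.frame(time_ms = seq_len(n_steps_total(config)) * dt)
    for (nm in names(trace_cols)) trace[[nm]] <- res[[trace_cols[[nm]]]]
  }
  list(spikes = spike_train(times, t_start = t0, t_stop = t1),
       state = state, trace = trace)
}

#' Simulate an AMAT model neuron
#'
#' Exact-integration (propagator) update of the linear subthreshold dynamics
#' with exponentially decaying synaptic currents, plus the multi-timescale
#' adaptive threshold: after every output spike the threshold jumps by
#' `alpha1` and `alpha2`, decaying with `tau_1` and `tau_2`; an additional
#' voltage-coupled component with gain `beta` and time constant `tau_v`
#' tracks the membrane potential. The membrane potential is not reset at
#' spikes; spiking is suppressed within `tau_ref` of the last spike (minimal
#' inter-spike interval is exactly `tau_ref`).
#'
#' @param params an `amat_params` object.
#' @param input_spikes optional data frame (time ms, weight pA); positive
#'   weights enter the excitatory synaptic current (`tau_syn_e`), negative
#'   weights the inhibitory one (`tau_syn_i`).
#' @param poisson_input optional `list(rate =, w =)` in-loop Poisson stimulus
#'   as in [simulate_izhikevich()], with `w` in pA.
#' @param current optional injected-current vector in pA, one value per step.
#' @param noise_spikes background noise: a `noise_preset` (Poisson event
#'   trains at rates `nu_e`, `nu_i` with weights 1 and -4/3 pA generated in
#'   the loop), or an explicit `list(times_e =, times_i =)` of event times in
#'   ms, or `NULL`.
#' @param config a [simulation_config()].
#' @param state optional carried-over state from a previous run (as returned
#'   in `$state`); when absent, `V(0) ~ U(-70, -65)` mV with all synaptic and
#'   threshold components at rest.
#' @return list with `spikes`, `state` (`v`, `ie`, `ii`, `th1`, `th2`, `thv`,
#'   `ref`), and `trace` (`time_ms`, `v_mV`, `theta_mV` when recording).
#' @export
simulate_amat <- function(params, input_spikes = NULL, poisson_input = NULL,
                          current = NULL, noise_spikes = NULL, config,
                          state = NULL) {
  stopifnot(inherits(params, "amat_params"),
            inherits(config, "simulation_config"))
  n <- n_steps_total(config)
  dt <- config$dt
  d_ie <- d_ii <- numeric(0)
  if (!is.null(input_spikes) && NROW(input_spikes)) {
    wts <- as.numeric(input_spikes[[2]])
    exc <- wts >= 0
    if (any(exc)) d_ie <- spikes_to_bins(input_spikes[exc, , drop = FALSE], dt, n)
    if (any(!exc)) d_ii <- spikes_to_bins(input_spikes[!exc, , drop = FALSE], dt, n)
  }
  p <- if (is.null(poisson_input)) numeric(0) else
    rate_to_p(poisson_input$rate, dt, n)
  w_stim <- if (is.null(poisson_input)) 0 else as.numeric(poisson_input$w)
  if (!is.null(current) && length(current) != n)
    stopf("current trace must have %d steps", n)
  use_bg <- FALSE
  nu_e_bin <- nu_i_bin <- 0
  w_e_bg <- 1
  w_i_bg <- -4 / 3
  if (inherits(noise_spikes, "noise_preset")) {
    if (noise_spikes$name != "none") {
      use_bg <- TRUE
      nu_e_bin <- noise_spikes$nu_e * dt / 1000
      nu_i_bin <- noise_spikes$nu_i * dt / 1000
      w_e_bg <- noise_spikes$w_e_bg
      w_i_bg <- noise_spikes$w_i_bg
    }
  } else if (is.list(noise_spikes) && !is.null(noise_spikes$times_e)) {
    ev_e <- spikes_to_bins(data.frame(time = noise_spikes$times_e,
                                      weight = rep(w_e_bg, length(noise_spikes$times_e))),
                           dt, n)
    ev_i <- spikes_to_bins(data.frame(time = noise_spikes$times_i %||% numeric(0),
                                      weight = rep(w_i_bg, length(noise_spikes$times_i %||% numeric(0)))),
                           dt, n)
    d_ie <- if (length(d_ie)) d_ie + ev_e else ev_e
    d_ii <- if (length(d_ii)) d_ii + ev_i else ev_i
  }

  with_seed(config$seed, {
    if (is.null(state)) {
      state <- list(v = stats::runif(1, -70, -65), ie = 0, ii = 0,
                    th1 = 0, th2 = 0, thv = 0, ref = 0L)
    }
    res <- amat_kernel(params$alpha1, params$alpha2, params$beta,
                       params$e_l, params$omega, params$c_m,
                       params$tau_m, params$tau_1, params$tau_2, params$tau_v,
                       params$tau_ref, params$tau_syn_e, params$tau_syn_i,
                       current %||% numeric(0), d_ie, d_ii, p, w_stim,
                       nu_e_bin, nu_i_bin, w_e_bg, w_i_bg, use_bg,
                       state$v, state$ie, state$ii,
                       state$th1, state$th2, state$thv, as.integer(state$ref),
                       dt, n, config$record_voltage)
    finish_sim(res, config,
               trace_cols = c(v_mV = "v_trace", theta_mV = "theta_trace"),
               state = res[c("v", "ie", "ii", "th1", "th2", "thv", "ref")])
  })
}

#' Threshold synaptic weight of the AMAT model
#'
#' The minimal excitatory weight for which the peak of a single-spike
#' postsynaptic potential from rest reaches the resting threshold `omega`.
#' The subthreshold dynamics are linear, so the peak scales linearly in the
#' weight and the threshold weight follows in closed form from the
#' double-exponential PSP of a first-order membrane driven by an exponential
#' synaptic current. The voltage-dependent threshold component is ignored
#' (the crossing is measured against the static `omega`), which makes the
#' value identical for all variants of the class.
#'
#' @param params an `amat_params` object.
#' @return threshold weight in pA (about 1.29e3 pA for the common parameters).
#' @export
compute_w_theta_amat <- function(params) {
  stopifnot(inherits(params, "amat_params"))
  gap <- params$omega - params$e_l
  if (gap <= 0) stopf("omega - E_L must be positive (got %g mV)", gap)
  tm <- params$tau_m
  ts <- params$tau_syn_e
  tpk <- log(tm / ts) * tm * ts / (tm - ts)
  peak_per_pa <- (ts * tm / (tm - ts)) * (exp(-tpk / tm) - exp(-tpk / ts)) /
    params$c_m
  gap / peak_per_pa
}

#' Approximate Gaussian white-noise current trace
#'
#' Piecewise-constant current redrawn independently every `dt` with mean `mu`
#' and standard deviation `sigma` as given (no `1/sqrt(dt)` scaling: the
#' effective diffusion therefore depends on `dt`, matching the convention the
#' published noise values are tied to).
#'
#' @param mu,sigma mean and standard deviation (unitless for the Izhikevich
#'   class, pA for current-based use).
#' @param dt time step in ms.
#' @param T duration in ms.
#' @param seed optional seed.
#' @return numeric vector of `round(T/dt)` per-step current values.
#' @export
gaussian_noise_current <- function(mu, sigma, dt = 0.1, T, seed = NULL) {
  check_scalar(sigma, "sigma", lower = 0)
  check_scalar(T, "T", lower = dt)
  n <- as.integer(round(T / dt))
  with_seed(seed, stats::rnorm(n, mean = mu, sd = sigma))
}

#' Simulate an ensemble of independently driven model neurons
#'
#' Runs `n` mutually independent neuron simulations, each driven by its own
#' realization of an inhomogeneous Poisson stimulus train (and background
#' noise), and returns the output spike trains. This is the workhorse behind
#' activation-function, transfer-function and stepped-Poisson measurements.
#'
#' @param spec a [model_spec()].
#' @param n number of neurons / trials.
#' @param rate stimulus rate: scalar (s^-1), function of time (ms, from
#'   simulation start including equilibration) or per-bin vector.
#' @param w synaptic weight in class-native sweep units: fraction of `xi` for
#'   the Izhikevich class, pA for the AMAT class.
#' @param noise a [noise_preset()] for the matching class (or `NULL`).
#' @param config a [simulation_config()]; its `seed` governs the whole
#'   ensemble.
#' @return list of `n` [spike_train()] objects over the recording window.
#' @export
simulate_ensemble <- function(spec, n, rate, w, noise = NULL, config) {
  if (inherits(spec, "rate_surrogate_spec")) {
    nt <- n_steps_total(config)
    dt <- config$dt
    rb <- if (is.function(rate)) rate((seq_len(nt) - 0.5) * dt)
          else if (length(rate) == 1L) rep(as.numeric(rate), nt)
          else rate
    out_rate <- spec$rate_fn(rb, dt)
    p <- pmax(0, out_rate) * dt / 1000
    if (any(p > 1)) stopf("surrogate rate too high for the grid")
    t0 <- config$equilibration
    t1 <- t0 + config$T
    return(with_seed(config$seed, lapply(seq_len(n), function(i) {
      tm <- bernoulli_bins(p) * dt
      spike_train(tm[tm >= t0 & tm < t1], t_start = t0, t_stop = t1)
    })))
  }
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(noise)) noise <- noise_preset("none", spec$class)
  run1 <- function() {
    if (spec$class == "izhikevich") {
      simulate_izhikevich(spec$params,
                          poisson_input = list(rate = rate, w = w * spec$params$xi),
                          noise = noise,
                          config = simulation_config(config$T, config$dt,
                                                     config$equilibration))$spikes
    } else {
      simulate_amat(spec$params,
                    poisson_input = list(rate = rate, w = w),
                    noise_spikes = noise,
                    config = simulation_config(config$T, config$dt,
                                               config$equilibration))$spikes
    }
  }
  with_seed(config$seed, lapply(seq_len(n), function(i) run1()))
}

#' Rate-surrogate responder for ground-truth checks
#'
#' A stand-in "model" whose output spike trains are inhomogeneous Poisson
#' realizations of a known transformation of the input rate profile. Used to
#' validate the measurement pipeline against constructed ground truth (e.g.
#' a linear-time-invariant responder with a known filter, or a responder
#' that reproduces an LN model's own prediction).
#'
#' @param rate_fn function `(rate_bins, dt) -> output rate bins` (s^-1) over
#'   the full simulation grid (equilibration included).
#' @param label label used in records.
#' @return object of classes `rate_surrogate_spec` that [simulate_ensemble()]
#'   (and the measurement functions built on it) accept in place of a
#'   [model_spec()].
#' @export
rate_surrogate_spec <- function(rate_fn, label = "surrogate") {
  structure(list(rate_fn = match.fun(rate_fn), label = label,
                 class = "surrogate"),
            class = "rate_surrogate_spec")
}
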