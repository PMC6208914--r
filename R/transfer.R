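#' Standard transfer-function frequency grid
#'
#' 28 stimulation frequencies, logarithmically spaced from 1 Hz to 1000 Hz.
#'
#' @return numeric vector of 28 frequencies in Hz.
#' @export
tf_frequency_grid <- function() {
  10^seq(0, 3, length.out = 28L)
}

#' Measure the empirical transfer function of a spiking model
#'
#' For each stimulation frequency, drives an ensemble of model neurons with
#' sinusoidally modulated Poisson input `a(t) = a0 + a1 sin(2 pi f t)` (phase
#' zero at recording onset, after equilibration), decomposes the pooled
#' response into harmonics, and assembles the complex transfer function
#' `H0(f) = (r1(f)/a1) e^{i phi(f)}`. The phase convention is relative to the
#' input phasor: a memoryless positive gain gives `H0` real and positive,
#' consistent with [eval_filter()].
#'
#' Each recording spans an integer number of stimulus periods (at least
#' `min_periods`, and at least `min_duration`); the stimulus frequency is
#' snapped to the simulation grid (relative shift below 1e-5). A point is
#' `valid` when the first harmonic is significant. When no point is valid
#' and the overall mean rate is below 1 s^-1, the estimate is flagged
#' missing (insufficient spiking to identify a filter).
#'
#' @param spec a [model_spec()].
#' @param noise a [noise_preset()].
#' @param w synaptic weight (class-native units, see [simulate_ensemble()]).
#' @param a0,a1 working point: mean rate and modulation depth in s^-1
#'   (`a1 <= a0`).
#' @param freqs frequency grid in Hz (default [tf_frequency_grid()]).
#' @param n_trials trials per frequency (default 1024).
#' @param min_periods minimum number of stimulus periods per trial.
#' @param min_duration minimum recording duration per trial in ms.
#' @param dt time step in ms.
#' @param equilibration equilibration per trial in ms.
#' @param seed optional seed.
#' @return object of class `transfer_function_estimate`: data frame with
#'   `f`, `f_eff`, `H` (complex), `r0`, `r1`, `phi1`, `r2`, `r_crit1`,
#'   `significant2`, `valid`; metadata in attributes (`missing` flag,
#'   working point, model, noise, weight).
#' @export
measure_transfer_function <- function(spec, noise, w, a0, a1,
                                      freqs = tf_frequency_grid(),
                                      n_trials = 1024, min_periods = 8,
                                      min_duration = 1000, dt = 0.1,
                                      equilibration = 1000, seed = NULL) {
  stopifnot(inherits(spec, "model_spec") || inherits(spec, "rate_surrogate_spec"))
  if (a1 > a0) stopf("modulation depth a1 = %g exceeds a0 = %g", a1, a0)
  with_seed(seed, {
    rows <- lapply(freqs, function(f) {
      n_per <- max(min_periods, ceiling(f * min_duration / 1000))
      n_rec <- as.integer(round(n_per / f * 1000 / dt))
      f_eff <- n_per / (n_rec * dt / 1000)
      n_eq <- as.integer(round(equilibration / dt))
      n_tot <- n_eq + n_rec
      tt <- (seq_len(n_tot) - 0.5) * dt - equilibration
      rate_bins <- a0 + a1 * sin(2 * pi * f_eff * tt / 1000)
      cfg <- simulation_config(T = n_rec * dt, dt = dt,
                               equilibration = equilibration)
      trains <- simulate_ensemble(spec, n = n_trials, rate = rate_bins,
                                  w = w, noise = noise, config = cfg)
      counts <- numeric(as.integer(round(n_rec * dt / 0.1)))
      nb <- length(counts)
      for (tr in trains) {
        if (length(tr$times)) {
          bin <- pmin(pmax(floor((tr$times - tr$t_start) / 0.1), 0), nb - 1L)
          counts <- counts + tabulate(bin + 1L, nbins = nb)
        }
      }
      hs <- harmonics_counts(counts, 0.1, n_trials, f_eff, M = 2)
      data.frame(f = f, f_eff = f_eff, r0 = hs$r0,
                 r1 = hs$r_m[1], phi1 = hs$phi_m[1], r2 = hs$r_m[2],
                 r_crit1 = hs$r_crit[1],
                 significant2 = isTRUE(hs$significant[2]),
                 valid = isTRUE(hs$significant[1]))
    })
    df <- do.call(rbind, rows)
    # input is a sine, response read in cosine convention: rotate by +pi/2
    df$H <- df$r1 / a1 * exp(1i * (df$phi1 + pi / 2))
    missing_flag <- !any(df$valid) && mean(df$r0) < 1
    structure(df, class = c("transfer_function_estimate", "data.frame"),
              missing = missing_flag,
              a0 = a0, a1 = a1, model = spec$label, model_class = spec$class,
              noise = noise$name %||% "custom", w = w)
  })
}

#' @export
print.transfer_function_estimate <- function(x, ...) {
  cat(sprintf("<transfer_function_estimate> %d frequencies, %d valid%s\n",
              nrow(x), sum(x$valid),
              if (isTRUE(attr(x, "missing"))) " [missing: insufficient response]" else ""))
  print.data.frame(utils::head(as.data.frame(x)[c("f", "r0", "r1", "r2", "valid")], 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
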