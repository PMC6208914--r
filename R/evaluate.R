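#' Fit quality between a rate-model and a spiking-model response
#'
#' The mean squared difference between the two rate traces normalized by the
#' variance of the spiking response,
#' `Ebar_r = integral (r_rate - r_spike)^2 dt / integral (r_spike -
#' mean(r_spike))^2 dt`, reported as the bounded score
#' `Er = 1 / (1 + Ebar_r)` in (0, 1]: `Er = 1` is perfect agreement,
#' `Er = 1/2` an error equal to the variance. Integrals use the rectangle
#' rule on the common grid.
#'
#' @param r_rate rate-model prediction (s^-1) on the common grid.
#' @param r_spike spiking-model rate estimate (s^-1) on the same grid.
#' @param dt grid step in ms (only needed with `t_min > 0`).
#' @param t_min drop the first `t_min` ms of both traces before scoring
#'   (kernel warm-up window); default 0 integrates the full traces.
#' @return `Er` in (0, 1], or flagged `NA` when `r_spike` has zero variance.
#' @export
fit_quality_er <- function(r_rate, r_spike, dt = 0.1, t_min = 0) {
  if (length(r_rate) != length(r_spike))
    stopf("traces must be on a common grid (%d vs %d samples)",
          length(r_rate), length(r_spike))
  if (t_min > 0) {
    drop <- min(length(r_rate) - 2L, as.integer(floor(t_min / dt)))
    if (drop > 0) {
      r_rate <- r_rate[-seq_len(drop)]
      r_spike <- r_spike[-seq_len(drop)]
    }
  }
  den <- sum((r_spike - mean(r_spike))^2)
  if (den <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero-variance spiking response"
    return(out)
  }
  ebar <- sum((r_rate - r_spike)^2) / den
  1 / (1 + ebar)
}

#' Score LN models against spiking responses to stepped Poisson input
#'
#' Simulates a population of independent model neurons driven by Poisson
#' spike trains whose rate follows a piecewise-constant schedule (default:
#' the 100/200/40/150 s^-1 test profile), pools the output trains into a
#' kernel-density rate estimate, and scores each candidate LN model's
#' prediction (driven by the known schedule rate) with [fit_quality_er()].
#' The experiment is repeated with `n_seeds` random seeds; seeds whose
#' optimal KDE width exceeds 15 ms are discarded, and the recorded `Er` is
#' the mean over the remaining seeds. Unresponsive conditions yield a missing
#' record rather than an error.
#'
#' During equilibration the population is driven at the schedule's first
#' rate, so the LN predictions start from the matching stationary state; by
#' default the first `delta + 3 tau_2` ms of each comparison are excluded
#' from the score (set `exclude_transient = FALSE` to integrate from 0).
#'
#' @param spec a [model_spec()].
#' @param ln_models list of [ln_model()] objects (typically the 20 working-
#'   point fits for this condition); names or provenance identify them.
#' @param noise a [noise_preset()].
#' @param w synaptic weight (class-native units).
#' @param schedule a [rate_schedule()].
#' @param n_neurons population size per seed (default 4096).
#' @param n_seeds number of repetitions (default 5).
#' @param dt simulation step in ms.
#' @param equilibration equilibration in ms.
#' @param exclude_transient drop the kernel warm-up window from the score.
#' @param seed optional master seed.
#' @return data frame of fit-quality records: one row per LN model with its
#'   provenance (`a0`, `a1`), `er`, `valid`, `n_seeds_used`.
#' @export
stepped_poisson_test <- function(spec, ln_models, noise, w,
                                 schedule = default_rate_schedule(),
                                 n_neurons = 4096, n_seeds = 5, dt = 0.1,
                                 equilibration = 1000,
                                 exclude_transient = TRUE, seed = NULL) {
  stopifnot(inherits(spec, "model_spec") || inherits(spec, "rate_surrogate_spec"))
  T <- schedule$t_end[nrow(schedule)] - schedule$t_start[1]
  n_eq <- as.integer(round(equilibration / dt))
  n_rec <- as.integer(round(T / dt))
  rate_bins <- c(rep(schedule$rate[1], n_eq),
                 schedule_bins(schedule, dt, n_rec))
  kde_bin <- 0.05
  a_fine <- schedule_bins(schedule, kde_bin,
                          as.integer(round(T / kde_bin)))
  er_mat <- matrix(NA_real_, nrow = length(ln_models), ncol = n_seeds)
  used <- logical(n_seeds)
  with_seed(seed, {
    for (s in seq_len(n_seeds)) {
      trains <- simulate_ensemble(spec, n = n_neurons, rate = rate_bins,
                                  w = w, noise = noise,
                                  config = simulation_config(T, dt,
                                                             equilibration))
      est <- tryCatch(suppressWarnings(kde_rate(trains, bin_width = kde_bin)),
                      error = function(e) NULL)
      if (is.null(est) || !est$valid) next
      used[s] <- TRUE
      for (i in seq_along(ln_models)) {
        m <- ln_models[[i]]
        pred <- predict_convolution(m, a_fine, dt = kde_bin,
                                    init = "stationary")
        tmin <- if (exclude_transient)
          m$filter$delta + 3 * m$filter$tau_2 else 0
        er_mat[i, s] <- fit_quality_er(pred, est$rate, dt = kde_bin,
                                       t_min = tmin)
      }
    }
  })
  recs <- lapply(seq_along(ln_models), function(i) {
    pv <- ln_models[[i]]$provenance
    ers <- er_mat[i, used]
    data.frame(model = spec$label, class = spec$class,
               noise = noise$name %||% "custom", w = w,
               a0 = pv$a0 %||% NA_real_, a1 = pv$a1 %||% NA_real_,
               stimulus = "stepped_poisson",
               er = if (any(is.finite(ers))) mean(ers[is.finite(ers)])
                    else NA_real_,
               valid = any(is.finite(ers)),
               n_seeds_used = sum(used))
  })
  do.call(rbind, recs)
}

#' Score LN models against spiking responses to arbitrary input spike trains
#'
#' Drives one model neuron per input train, pools the output spike trains
#' into a KDE rate estimate, and scores each LN model's prediction.
#' The LN input rate is the known `input_rate` when given (s^-1 on the
#' KDE grid), otherwise it is estimated from the input trains by
#' [kde_rate()]. Used for realistic (retinal-ganglion-cell-like) test
#' stimuli.
#'
#' @param spec a [model_spec()].
#' @param ln_models list of [ln_model()] objects.
#' @param trains list of input [spike_train()] objects (one neuron each).
#' @param noise a [noise_preset()].
#' @param w synaptic weight (class-native units).
#' @param input_rate optional known input rate on the 0.05 ms grid.
#' @param n_seeds repetitions with different simulation seeds.
#' @param dt simulation step in ms.
#' @param equilibration equilibration in ms (the input trains are applied
#'   after it; no stimulus during equilibration).
#' @param exclude_transient drop the kernel warm-up window from the score.
#' @param seed optional master seed.
#' @return data frame of fit-quality records as in [stepped_poisson_test()].
#' @export
spike_train_test <- function(spec, ln_models, trains, noise, w,
                             input_rate = NULL, n_seeds = 5, dt = 0.1,
                             equilibration = 1000, exclude_transient = TRUE,
                             seed = NULL) {
  stopifnot(inherits(spec, "model_spec") || inherits(spec, "rate_surrogate_spec"))
  T <- train_duration(trains[[1]])
  kde_bin <- 0.05
  if (is.null(input_rate)) {
    in_est <- suppressWarnings(kde_rate(trains, bin_width = kde_bin))
    input_rate <- in_est$rate
  }
  n <- as.integer(round((T + equilibration) / dt))
  er_mat <- matrix(NA_real_, nrow = length(ln_models), ncol = n_seeds)
  used <- logical(n_seeds)
  with_seed(seed, {
    for (s in seq_len(n_seeds)) {
      out <- lapply(trains, function(tr) {
        sp <- data.frame(time = tr$times - tr$t_start + equilibration,
                         weight = if (spec$class == "izhikevich")
                           rep(w * spec$params$xi, length(tr$times))
                         else rep(w, length(tr$times)))
        cfg <- simulation_config(T, dt, equilibration)
        if (spec$class == "izhikevich")
          simulate_izhikevich(spec$params, input_spikes = sp, noise = noise,
                              config = cfg)$spikes
        else
          simulate_amat(spec$params, input_spikes = sp, noise_spikes = noise,
                        config = cfg)$spikes
      })
      est <- tryCatch(suppressWarnings(kde_rate(out, bin_width = kde_bin)),
                      error = function(e) NULL)
      if (is.null(est) || !est$valid) next
      used[s] <- TRUE
      for (i in seq_along(ln_models)) {
        m <- ln_models[[i]]
        pred <- predict_convolution(m, input_rate, dt = kde_bin,
                                    init = "stationary")
        tmin <- if (exclude_transient)
          m$filter$delta + 3 * m$filter$tau_2 else 0
        er_mat[i, s] <- fit_quality_er(pred, est$rate, dt = kde_bin,
                                       t_min = tmin)
      }
    }
  })
  recs <- lapply(seq_along(ln_models), function(i) {
    pv <- ln_models[[i]]$provenance
    ers <- er_mat[i, used]
    data.frame(model = spec$label, class = spec$class,
               noise = noise$name %||% "custom", w = w,
               a0 = pv$a0 %||% NA_real_, a1 = pv$a1 %||% NA_real_,
               stimulus = "spike_trains",
               er = if (any(is.finite(ers))) mean(ers[is.finite(ers)])
                    else NA_real_,
               valid = any(is.finite(ers)),
               n_seeds_used = sum(used))
  })
  do.call(rbind, recs)
}

#' Select the optimal LN model for one input condition
#'
#' The optimal model for a given (model, noise, weight) condition is the one
#' with the highest `Er` across all working-point combinations
#' (`Er_opt = max over (a0, a1) of Er`).
#'
#' @param records data frame of fit-quality records (rows for one
#'   condition).
#' @return the record row with maximal `er`, or `NULL` when no record is
#'   valid.
#' @export
select_optimal <- function(records) {
  ok <- which(records$valid & is.finite(records$er))
  if (!length(ok)) return(NULL)
  records[ok[which.max(records$er[ok])], , drop = FALSE]
}

#' Generalization quality relative to the optimal model
#'
#' `rho_X = Er_X / Er_opt` measures how close a generalized model's fit
#' quality comes to the optimal per-condition model; `rho = 1` is best, and
#' values above 1 are possible when a generalization outperforms the
#' specific fit.
#'
#' @param er_x fit quality of generalization X.
#' @param er_opt optimal per-condition fit quality (`> 0`).
#' @return `rho`, or `NA` when either score is missing.
#' @export
generalization_quality <- function(er_x, er_opt) {
  if (is.null(er_x) || is.null(er_opt) || is.na(er_x) || is.na(er_opt))
    return(NA_real_)
  if (er_opt <= 0) stopf("er_opt must be positive")
  er_x / er_opt
}
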