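#' Standard working-point grid
#'
#' The 20 combinations of mean input rate and modulation depth around which
#' linear filters are identified: `a0` in {50, 100, 200, 400, 800} s^-1
#' crossed with `a1 = {0.25, 0.5, 0.75, 1} a0`.
#'
#' @return data frame with columns `a0`, `a1`.
#' @export
working_point_grid <- function() {
  a0 <- c(50, 100, 200, 400, 800)
  do.call(rbind, lapply(a0, function(a)
    data.frame(a0 = a, a1 = c(0.25, 0.5, 0.75, 1) * a)))
}

#' Run the full LN reduction for one input condition
#'
#' Chains the whole per-condition workflow: measure the activation function,
#' measure transfer functions at every working point, fit the bandpass
#' filter, assemble LN models, score them against the stepped-Poisson test
#' stimulus, and select the optimal working point. Problem sizes (trials,
#' population, seeds) are exposed so the sweep can be run at reduced scale.
#'
#' @param spec a [model_spec()].
#' @param noise a [noise_preset()].
#' @param w synaptic weight (class-native units).
#' @param working_points data frame with columns `a0`, `a1` (default
#'   [working_point_grid()]).
#' @param act_duration activation measurement duration per knot (ms).
#' @param a0_grid activation knot grid (s^-1).
#' @param tf_trials trials per transfer-function frequency.
#' @param fit_starts multi-start count for the filter fit.
#' @param n_neurons,n_seeds stepped-test population size and repetitions.
#' @param seed master seed; the whole pipeline is deterministic given it.
#' @return list with `activation`, `fits` (data frame of filter parameters
#'   per working point), `ln_models`, `records` (stepped-test scores),
#'   `optimal` (best record or `NULL`) and `er_opt`.
#' @export
run_ln_pipeline <- function(spec, noise, w,
                            working_points = working_point_grid(),
                            act_duration = 10000,
                            a0_grid = seq(0, 1000, by = 10),
                            tf_trials = 1024, fit_starts = 60,
                            n_neurons = 4096, n_seeds = 5, seed = NULL) {
  with_seed(seed, {
    act <- measure_activation_function(spec, noise, w, a0_grid = a0_grid,
                                       duration = act_duration)
    ln_models <- list()
    fit_rows <- list()
    for (i in seq_len(nrow(working_points))) {
      a0 <- working_points$a0[i]
      a1 <- working_points$a1[i]
      tf <- measure_transfer_function(spec, noise, w, a0 = a0, a1 = a1,
                                      n_trials = tf_trials)
      if (isTRUE(attr(tf, "missing")) || sum(tf$valid) < 8L) next
      ft <- tryCatch(fit_filter(tf, n_starts = fit_starts,
                                n_starts_lowpass = max(5L, fit_starts %/% 4L)),
                     error = function(e) NULL)
      if (is.null(ft)) next
      m <- ln_model(act, ft$params,
                    provenance = list(a0 = a0, a1 = a1, model = spec$label,
                                      noise = noise$name, w = w))
      ln_models[[length(ln_models) + 1L]] <- m
      fit_rows[[length(fit_rows) + 1L]] <-
        data.frame(model = spec$label, class = spec$class, noise = noise$name,
                   w = w, a0 = a0, a1 = a1,
                   gamma1 = ft$params$gamma1, gamma2 = ft$params$gamma2,
                   f_c1 = ft$params$f_c1, f_c2 = ft$params$f_c2,
                   delta = ft$params$delta,
                   loss = ft$loss, loss_lowpass = ft$lowpass$loss)
    }
    fits <- if (length(fit_rows)) do.call(rbind, fit_rows) else NULL
    records <- NULL
    optimal <- NULL
    if (length(ln_models)) {
      records <- stepped_poisson_test(spec, ln_models, noise, w,
                                      n_neurons = n_neurons,
                                      n_seeds = n_seeds)
      optimal <- select_optimal(records)
    }
    list(activation = act, fits = fits, ln_models = ln_models,
         records = records, optimal = optimal,
         er_opt = if (is.null(optimal)) NA_real_ else optimal$er)
  })
}
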