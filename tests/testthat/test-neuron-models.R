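test_that("parameter presets match the published study set", {
  expect_length(model_variants("izhikevich"), 14L)
  expect_length(model_variants("amat"), 18L)
  expect_false(any(c("G", "I", "L", "O", "R", "T") %in%
                     model_variants("izhikevich")))
  expect_false(any(c("L", "R") %in% model_variants("amat")))
  a <- izhikevich_params("A")
  expect_equal(c(a$a, a$b, a$c, a$d, a$xi, a$i_ext), c(0.02, 0.2, -65, 6, 15.1, 0))
  expect_equal(izhikevich_params("A")$v_th, 30)
  expect_gt(min(vapply(model_variants("izhikevich"),
                       function(l) izhikevich_params(l)$xi, 0)), 0)
  expect_error(izhikevich_params("G"), "excluded")
  q <- amat_params("Q")
  expect_equal(c(q$alpha1, q$alpha2, q$beta), c(25, -1, 0))
  expect_equal(c(q$e_l, q$omega, q$c_m, q$tau_m, q$tau_1, q$tau_2,
                 q$tau_v, q$tau_ref, q$tau_syn_e, q$tau_syn_i),
               c(-70, -65, 200, 10, 10, 200, 5, 2, 1, 3))
})

test_that("Izhikevich rest is a fixed point and single-spike excitability brackets xi", {
  p <- izhikevich_params("A")
  cfg <- simulation_config(T = 1000, equilibration = 0)
  rest <- list(v = -70, u = -14)
  r <- simulate_izhikevich(p, config = cfg, state = rest)
  expect_length(r$spikes$times, 0L)
  # a spike slightly above the weight factor triggers; a tenth of it does not
  hit <- simulate_izhikevich(p, input_spikes = data.frame(time = 10,
                                                          weight = 1.05 * p$xi),
                             config = cfg, state = rest)
  miss <- simulate_izhikevich(p, input_spikes = data.frame(time = 10,
                                                           weight = 0.1 * p$xi),
                              config = cfg, state = rest)
  expect_gte(length(hit$spikes$times), 1L)
  expect_length(miss$spikes$times, 0L)
})

test_that("Izhikevich integration is bit-identical to a direct Euler oracle", {
  set.seed(11)
  labs <- model_variants("izhikevich")
  for (i in 1:10) {
    prm <- izhikevich_params(sample(labs, 1))
    n <- 5000
    cur <- stats::rnorm(n, mean = stats::runif(1, 0, 8), sd = 2)
    jumps <- numeric(n)
    jumps[sample(n, 40)] <- stats::runif(40, 0, prm$xi)
    v0 <- stats::runif(1, -70, -50)
    res <- simulate_izhikevich(prm,
                               input_spikes = data.frame(
                                 time = (which(jumps != 0) - 1) * 0.1,
                                 weight = jumps[jumps != 0]),
                               current = cur,
                               config = simulation_config(T = n * 0.1,
                                                          equilibration = 0),
                               state = list(v = v0, u = prm$b * v0))
    orc <- izh_euler_oracle(prm, v0, prm$b * v0, cur, jumps, 0.1, n)
    expect_identical(res$spikes$times, (orc$spikes - 1L) * 0.1)
    expect_identical(res$state$v, orc$v)
    expect_identical(res$state$u, orc$u)
  }
})

test_that("Izhikevich divergence is reported with the step time", {
  bad <- structure(list(a = 0, b = 0, c = -65, d = 0, xi = 1, i_ext = 1e12,
                        v_th = Inf, label = "X", name = "divergent"),
                   class = "izhikevich_params")
  expect_error(simulate_izhikevich(bad,
                                   config = simulation_config(T = 10,
                                                              equilibration = 0),
                                   state = list(v = -70, u = 0)),
               "diverged at t")
})

test_that("AMAT rest is an equilibrium and the subthreshold PSP is exact", {
  p <- amat_params("A")
  cfg <- simulation_config(T = 300, equilibration = 0, record_voltage = TRUE)
  rest <- list(v = -70, ie = 0, ii = 0, th1 = 0, th2 = 0, thv = 0, ref = 0)
  r0 <- simulate_amat(p, config = cfg, state = rest)
  expect_length(r0$spikes$times, 0L)
  expect_true(all(abs(r0$trace$v_mV + 70) < 1e-12))
  # closed-form double-exponential PSP, single 200 pA input spike (beta = 0)
  r <- simulate_amat(p, input_spikes = data.frame(time = 50, weight = 200),
                     config = cfg, state = rest)
  th <- amat_psp_oracle(r$trace$time_ms, 50, 200)
  expect_lt(max(abs(r$trace$v_mV + 70 - th)), 1e-6)
})

test_that("AMAT subthreshold trajectory matches the analytic solution for arbitrary input", {
  p <- amat_params("A")  # beta = 0
  cfg <- simulation_config(T = 400, equilibration = 0, record_voltage = TRUE)
  set.seed(21)
  for (rep in 1:3) {
    tms <- sort(sample(seq(0, 350, by = 0.1), 25))
    wts <- stats::runif(25, -40, 40)  # small weights: stay subthreshold
    r <- simulate_amat(p, input_spikes = data.frame(time = tms, weight = wts),
                       config = cfg,
                       state = list(v = -70, ie = 0, ii = 0, th1 = 0,
                                    th2 = 0, thv = 0, ref = 0))
    expect_length(r$spikes$times, 0L)
    th <- rep(0, nrow(r$trace))
    for (k in seq_along(tms)) {
      tau_s <- if (wts[k] >= 0) 1 else 3
      th <- th + amat_psp_oracle(r$trace$time_ms,
                                 floor(tms[k] / 0.1 + 1e-6) * 0.1,
                                 wts[k], tau_s = tau_s)
    }
    expect_lt(max(abs(r$trace$v_mV + 70 - th)), 1e-6)
  }
})

test_that("AMAT threshold weight follows from the PSP peak and is variant-independent", {
  p <- amat_params("A")
  w_theta <- compute_w_theta_amat(p)
  expect_equal(w_theta, 1291.55, tolerance = 1e-3)
  # bisection against an independent fine-grid numeric PSP peak
  peak1 <- amat_psp_peak_numeric()
  lo <- 100
  hi <- 5000
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (mid * peak1 >= p$omega - p$e_l) hi <- mid else lo <- mid
  }
  expect_equal(w_theta, hi, tolerance = 1e-3)
  # stimulus weights 100-900 pA span roughly 8-70% of w_theta
  expect_lt(100 / w_theta, 0.10)
  expect_lt(900 / w_theta, 0.75)
  expect_gt(900 / w_theta, 0.60)
  # doubling omega - E_L doubles the weight (linear subthreshold dynamics)
  p2 <- p
  p2$omega <- p$e_l + 2 * (p$omega - p$e_l)
  expect_equal(compute_w_theta_amat(p2), 2 * w_theta, tolerance = 1e-12)
  # identical across all study-set variants
  ws <- vapply(model_variants("amat"),
               function(l) compute_w_theta_amat(amat_params(l)), 0)
  expect_true(all(abs(ws - w_theta) < 1e-9))
  p3 <- p
  p3$omega <- -70
  expect_error(compute_w_theta_amat(p3), "positive")
})

test_that("AMAT inter-spike intervals never fall below the refractory period", {
  p <- amat_params("A")
  r <- simulate_amat(p, poisson_input = list(rate = 3000, w = 900),
                     config = simulation_config(T = 2000, seed = 31))
  expect_gt(length(r$spikes$times), 100)
  expect_true(all(diff(r$spikes$times) >= p$tau_ref - 1e-9))
})

test_that("spike counts are invariant under splitting a run with carried-over state", {
  p <- izhikevich_params("C")
  n <- 10000
  cur <- rep(6, n)
  full <- simulate_izhikevich(p, current = cur,
                              config = simulation_config(T = 1000,
                                                         equilibration = 0),
                              state = list(v = -65, u = -13))
  h1 <- simulate_izhikevich(p, current = cur[1:5000],
                            config = simulation_config(T = 500,
                                                       equilibration = 0),
                            state = list(v = -65, u = -13))
  h2 <- simulate_izhikevich(p, current = cur[5001:10000],
                            config = simulation_config(T = 500,
                                                       equilibration = 0),
                            state = h1$state)
  expect_equal(length(full$spikes$times),
               length(h1$spikes$times) + length(h2$spikes$times))
  pa <- amat_params("F")
  ina <- data.frame(time = seq(5, 995, by = 5), weight = 600)
  fa <- simulate_amat(pa, input_spikes = ina,
                      config = simulation_config(T = 1000, equilibration = 0),
                      state = list(v = -70, ie = 0, ii = 0, th1 = 0, th2 = 0,
                                   thv = 0, ref = 0))
  s1 <- simulate_amat(pa, input_spikes = ina[ina$time < 500, ],
                      config = simulation_config(T = 500, equilibration = 0),
                      state = list(v = -70, ie = 0, ii = 0, th1 = 0, th2 = 0,
                                   thv = 0, ref = 0))
  ina2 <- ina[ina$time >= 500, ]
  ina2$time <- ina2$time - 500
  s2 <- simulate_amat(pa, input_spikes = ina2,
                      config = simulation_config(T = 500, equilibration = 0),
                      state = s1$state)
  expect_equal(length(fa$spikes$times),
               length(s1$spikes$times) + length(s2$spikes$times))
})

test_that("simulations are fully deterministic given a seed", {
  spec <- model_spec("amat", "E")
  np <- noise_preset("balanced", "amat")
  cfg <- simulation_config(T = 500, seed = 77)
  a <- simulate_amat(spec$params, poisson_input = list(rate = 300, w = 500),
                     noise_spikes = np, config = cfg)
  b <- simulate_amat(spec$params, poisson_input = list(rate = 300, w = 500),
                     noise_spikes = np, config = cfg)
  expect_identical(a$spikes$times, b$spikes$times)
  speci <- model_spec("izhikevich", "E")
  cfgi <- simulation_config(T = 500, seed = 78)
  ai <- simulate_izhikevich(speci$params,
                            poisson_input = list(rate = 300, w = 0.5 * 15.1),
                            noise = noise_preset("balanced", "izhikevich"),
                            config = cfgi)
  bi <- simulate_izhikevich(speci$params,
                            poisson_input = list(rate = 300, w = 0.5 * 15.1),
                            noise = noise_preset("balanced", "izhikevich"),
                            config = cfgi)
  expect_identical(ai$spikes$times, bi$spikes$times)
})

test_that("gaussian noise current has the requested moments and presets exist", {
  x <- gaussian_noise_current(0, 0, dt = 0.1, T = 100, seed = 1)
  expect_true(all(x == 0))
  y <- gaussian_noise_current(0, 0.1, dt = 0.1, T = 1e5, seed = 2)
  expect_length(y, 1e6L)
  expect_lt(abs(mean(y)), 4 * 0.1 / sqrt(1e6))
  expect_lt(abs(stats::sd(y) - 0.1) / 0.1, 0.01)
  # the three regimes as named presets, class-specific scales
  for (cls in c("izhikevich", "amat")) {
    expect_equal(noise_preset("none", cls)$sigma, 0)
    expect_equal(noise_preset("balanced", cls)$mu, 0)
    expect_lt(noise_preset("biased", cls)$mu, 0)
  }
  expect_equal(noise_preset("balanced", "izhikevich")$sigma, 0.1)
  expect_equal(noise_preset("biased", "izhikevich")$sigma, 0.2)
  expect_equal(noise_preset("balanced", "amat")$sigma, 100)
  expect_equal(noise_preset("biased", "amat")$mu, -100)
})
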