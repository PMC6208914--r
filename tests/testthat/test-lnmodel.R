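test_that("filter evaluation matches closed-form special cases and a symbolic oracle", {
  p <- filter_params(2, -1.4, 10, 60, 1)
  expect_equal(eval_filter(p, 0), complex(real = 2 * (1 - 1.4)))
  lp <- filter_params(3, 0, 50, 50, 0)
  expect_equal(Mod(eval_filter(lp, 50)), 3 / sqrt(2), tolerance = 1e-12)
  set.seed(101)
  b <- filter_frequency_bounds()
  for (i in 1:100) {
    g1 <- stats::runif(1, -10, 10)
    g2 <- stats::runif(1, -2, 2)
    fc <- sort(exp(stats::runif(2, log(b[1]), log(b[2]))))
    dl <- stats::runif(1, 0, 10)
    fp <- filter_params(g1, g2, fc[1], fc[2], dl)
    f <- stats::runif(1, 0, 1000)
    # independent re-derivation of the transfer formula
    direct <- g1 * exp(-2i * pi * f * dl / 1000) *
      (1 / (1 + 1i * f / fc[1]) + g2 / (1 + 1i * f / fc[2]))
    expect_equal(eval_filter(fp, f), direct, tolerance = 1e-12)
  }
})

test_that("frequency bounds derive from the admissible time constants", {
  b <- filter_frequency_bounds()
  expect_equal(unname(b[1]), 1000 / (2 * pi * 175))
  expect_equal(unname(b[2]), 1000 / (2 * pi * 0.25))
  expect_error(filter_params(1, 0, 0.5, 10, 0), "outside")
  expect_error(filter_params(1, 0, 10, 700, 0), "outside")
  expect_error(filter_params(1, 0, 10, 100, 80), "outside")
  expect_error(filter_params(1, 0.5, 100, 10, 0), "swap")
})

test_that("branch swapping restores frequency order without changing the filter", {
  sw <- swap_filter_branches(2, 0.5, 100, 10, 1.5)
  expect_equal(sw[c("gamma1", "gamma2", "f_c1", "f_c2")],
               list(gamma1 = 1.0, gamma2 = 2.0, f_c1 = 10, f_c2 = 100))
  set.seed(102)
  for (i in 1:20) {
    g1 <- stats::runif(1, -5, 5)
    g2 <- stats::runif(1, 0.1, 3) * sample(c(-1, 1), 1)
    fc <- exp(stats::runif(2, log(1), log(600)))
    raw <- list(gamma1 = g1, gamma2 = g2, f_c1 = fc[1], f_c2 = fc[2],
                delta = 2)
    sw <- swap_filter_branches(g1, g2, fc[1], fc[2], 2)
    f <- stats::runif(5, 0, 1000)
    expect_equal(eval_filter(sw, f), eval_filter(raw, f), tolerance = 1e-10)
    expect_lte(sw$f_c1, sw$f_c2)
  }
})

test_that("noiseless synthetic transfer functions are recovered by the fit", {
  truth <- filter_params(2, -1.4, 10, 60, 1)
  f <- tf_frequency_grid()
  tf <- list(f = f, H = eval_filter(truth, f))
  ft <- fit_filter(tf, n_starts = 30, seed = 7)
  for (nm in c("gamma1", "gamma2", "f_c1", "f_c2", "delta"))
    expect_equal(ft$params[[nm]], truth[[nm]], tolerance = 0.01)
  expect_lt(ft$loss, 1e-8)
  expect_lte(ft$loss, ft$lowpass$loss)
  # determinism given seed
  ft2 <- fit_filter(tf, n_starts = 30, seed = 7)
  expect_identical(unlist(ft$params), unlist(ft2$params))
  # too few valid points is an error
  expect_error(fit_filter(list(f = f[1:5], H = eval_filter(truth, f[1:5]))),
               ">= 8 valid")
})

test_that("fitted characteristic frequencies stay inside the admissible band", {
  set.seed(103)
  f <- tf_frequency_grid()
  b <- filter_frequency_bounds()
  for (i in 1:5) {
    truth <- list(gamma1 = stats::runif(1, 0.5, 3),
                  gamma2 = stats::runif(1, -1.5, 1.5),
                  f_c1 = exp(stats::runif(1, log(2), log(50))),
                  f_c2 = exp(stats::runif(1, log(60), log(500))),
                  delta = stats::runif(1, 0, 5))
    H <- eval_filter(truth, f) * (1 + 0.03 * stats::rnorm(28))
    ft <- fit_filter(list(f = f, H = H), n_starts = 20, seed = i)
    expect_gte(ft$params$f_c1, b[1] - 1e-6)
    expect_lte(ft$params$f_c2, b[2] + 1e-6)
    expect_lte(ft$params$f_c1, ft$params$f_c2)
    expect_lte(ft$loss, ft$lowpass$loss)
  }
})

test_that("LN kernel is causal, normalized, and Fourier-consistent at f = 0", {
  set.seed(104)
  for (i in 1:20) {
    g2 <- if (i == 1) -1.002 else stats::runif(1, -1.8, 2)
    if (abs(1 + g2) < 1e-3 && i > 1) g2 <- g2 + 0.01
    fp <- filter_params(stats::runif(1, 0.5, 3), g2,
                        exp(stats::runif(1, log(1), log(30))),
                        exp(stats::runif(1, log(40), log(600))),
                        stats::runif(1, 0, 5))
    kb <- lnspike:::ln_kernel_bins(fp, 0.1)
    expect_lt(abs(sum(kb$G) - 1), 1e-9)
    # time-domain integral of the unnormalized kernel equals H(0)
    expect_equal(sum(kb$G) * fp$gamma1 * (1 + fp$gamma2),
                 Re(eval_filter(fp, 0)), tolerance = 1e-9)
  }
  expect_error(ln_model(activation_function(c(0, 100), c(0, 50)),
                        list(gamma1 = 1, gamma2 = -1, f_c1 = 10, f_c2 = 60,
                             delta = 0)),
               "gamma2")
})

test_that("convolution prediction reduces to g(a0) for stationary input and rectifies", {
  g <- activation_function(seq(0, 1000, 100), 0.4 * seq(0, 1000, 100) - 20)
  m <- ln_model(g, filter_params(1, 0.5, 10, 100, 2))
  r <- predict_convolution(m, rep(300, 8000), dt = 0.1, init = "zero")
  expect_equal(tail(r, 1), eval_activation(g, 300), tolerance = 1e-9)
  # negative extrapolation of g is clipped at zero
  r0 <- predict_convolution(m, rep(10, 8000), dt = 0.1)
  expect_true(all(r0 >= 0))
  expect_equal(tail(r0, 1), 0)  # g(10) = -16 -> rectified
})

test_that("step response follows the closed-form double-exponential relaxation", {
  # identity-plus-offset activation keeps the rectifier inactive, so the
  # prediction exposes the filtered drive u(t) directly (as r - 1000)
  ident <- activation_function(c(-2000, 2000), c(-1000, 3000))
  step_truth <- function(fp, g2, n, ns, dt) {
    c1 <- 1 / (1 + g2)
    c2 <- g2 / (1 + g2)
    k <- seq_len(n) - ns
    ifelse(k <= 0, 100,
           300 - 200 * (c1 * exp(-k * dt / fp$tau_1) +
                          c2 * exp(-k * dt / fp$tau_2)))
  }
  n <- 20000
  ns <- 5000
  a <- c(rep(100, ns), rep(300, n - ns))
  for (g2 in c(0.8, -0.6)) {
    fp <- filter_params(1, g2, 8, 120, 0)
    m <- ln_model(ident, fp)
    u <- predict_convolution(m, a, dt = 0.1, init = "stationary") - 1000
    expect_lt(max(abs(u - step_truth(fp, g2, n, ns, 0.1))), 1e-6)
  }
  # near-singular normalization: the transient is huge, compare relatively
  fp <- filter_params(1, -1.002, 8, 120, 0)
  m <- ln_model(ident, fp)
  u <- predict_convolution(m, a, dt = 0.1, init = "stationary") - 1000
  truth <- step_truth(fp, -1.002, n, ns, 0.1)
  expect_lt(max(abs(u - truth)) / max(abs(truth)), 1e-9)
})

test_that("ODE and convolution predictions agree including near-singular gamma2", {
  set.seed(105)
  g <- activation_function(seq(0, 1000, 50), 0.5 * seq(0, 1000, 50))
  for (i in 1:12) {
    g2 <- c(-1.002, -0.95, 0, 1.5)[1 + (i %% 4)]
    fp <- filter_params(stats::runif(1, 0.5, 2), g2,
                        exp(stats::runif(1, log(2), log(30))),
                        exp(stats::runif(1, log(40), log(500))),
                        stats::runif(1, 0, 5))
    m <- ln_model(g, fp)
    a <- pmax(0, 300 + 100 * as.numeric(stats::filter(stats::rnorm(15000),
                                                      rep(0.05, 20),
                                                      sides = 1)))
    a[is.na(a)] <- 300
    p1 <- predict_convolution(m, a, dt = 0.1)
    p2 <- predict_ode(m, a, dt = 0.1)
    expect_lt(sqrt(mean((p1 - p2)^2)), 1e-4)
  }
  # stationary and zero-input fixed points of the ODE form
  m <- ln_model(g, filter_params(1, -0.5, 10, 100, 1))
  expect_equal(tail(predict_ode(m, rep(400, 10000)), 1),
               eval_activation(g, 400), tolerance = 1e-6)
  expect_equal(unique(predict_ode(m, rep(0, 100))),
               max(0, eval_activation(g, 0)))
})
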