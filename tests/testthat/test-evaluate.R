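test_that("fit quality Er matches closed-form and hand-computed values", {
  r <- c(0, 2, 4, 2)
  expect_equal(fit_quality_er(r, r), 1)
  expect_equal(fit_quality_er(rep(mean(r), 4), r), 0.5)
  expect_equal(fit_quality_er(c(1, 2, 3, 2), r), 0.8)  # Ebar = 2/8
  # zero-variance reference is flagged, not thrown
  z <- fit_quality_er(c(1, 2), c(3, 3))
  expect_true(is.na(z))
  expect_match(attr(z, "reason"), "variance")
  expect_error(fit_quality_er(1:3, 1:4), "common grid")
  # invariant under adding a common constant to both traces
  set.seed(120)
  a <- stats::runif(50)
  b <- stats::runif(50)
  expect_equal(fit_quality_er(a, b), fit_quality_er(a + 7, b + 7))
})

test_that("optimal-model selection is an argmax over working points", {
  recs <- data.frame(a0 = c(100, 200, 400), a1 = c(50, 100, 200),
                     er = c(0.3, 0.9, 0.7), valid = TRUE)
  expect_equal(select_optimal(recs)$er, 0.9)
  one <- recs[1, ]
  expect_equal(select_optimal(one)$a0, 100)
  # brute-force scan agreement on random tables
  set.seed(121)
  for (i in 1:20) {
    tab <- data.frame(a0 = 1:20, a1 = 1, er = stats::runif(20),
                      valid = stats::runif(20) > 0.2)
    opt <- select_optimal(tab)
    brute <- -Inf
    for (j in 1:20) if (tab$valid[j] && tab$er[j] > brute) brute <- tab$er[j]
    if (is.finite(brute)) expect_equal(opt$er, brute) else expect_null(opt)
  }
  expect_null(select_optimal(data.frame(er = NA_real_, valid = FALSE)))
})

test_that("generalization quality is the ratio to the optimal score", {
  expect_equal(generalization_quality(0.45, 0.9), 0.5)
  expect_equal(generalization_quality(0.9, 0.9), 1)
  expect_gt(generalization_quality(0.95, 0.9), 1)  # may exceed 1
  expect_true(is.na(generalization_quality(NA, 0.9)))
  expect_error(generalization_quality(0.5, 0), "positive")
})

make_fits_df <- function() {
  wp <- working_point_grid()
  do.call(rbind, lapply(c("none", "balanced"), function(nz)
    do.call(rbind, lapply(c(100, 300), function(w)
      data.frame(model = "A", noise = nz, w = w, a0 = wp$a0, a1 = wp$a1,
                 gamma1 = 2, gamma2 = -1.2, f_c1 = 10, f_c2 = 60,
                 delta = 1.5)))))
}

test_that("MNW generalization with identical parameter sets returns that set", {
  fits <- make_fits_df()
  acts <- expand.grid(model = "A", noise = c("none", "balanced"),
                      w = c(100, 300), a0 = seq(0, 1000, 250),
                      stringsAsFactors = FALSE)
  acts$r0 <- 0.1 * acts$a0 * acts$w / 100
  gs <- generalize(fits, acts, "MNW")
  m <- generalized_ln_model(gs, "A", "balanced", 300)
  expect_equal(m$filter$gamma1, 2)
  expect_equal(m$filter$gamma2, -1.2)
  expect_equal(m$filter$f_c1, 10)
  expect_equal(m$filter$delta, 1.5)
  # the per-condition activation spline is reused
  expect_equal(eval_activation(m$activation, 500), 0.1 * 500 * 3)
})

test_that("M-level pooling reproduces conditions whose activation scales with weight", {
  fits <- make_fits_df()
  acts <- expand.grid(model = "A", noise = c("none", "balanced"),
                      w = c(100, 300), a0 = seq(0, 1000, 100),
                      stringsAsFactors = FALSE)
  g0 <- function(a) 0.3 * a + 0.0002 * a^2
  acts$r0 <- acts$w * g0(acts$a0)
  gs <- generalize(fits, acts, "M")
  for (w in c(100, 300)) {
    m <- generalized_ln_model(gs, "A", "none", w)
    expect_equal(eval_activation(m$activation, seq(0, 1000, 100)),
                 w * g0(seq(0, 1000, 100)), tolerance = 1e-9)
  }
})

test_that("MNWS selects the stepped-test-optimal working point", {
  fits <- make_fits_df()
  fits$gamma1 <- seq_len(nrow(fits))  # make rows distinguishable
  acts <- expand.grid(model = "A", noise = c("none", "balanced"),
                      w = c(100, 300), a0 = c(0, 500, 1000),
                      stringsAsFactors = FALSE)
  acts$r0 <- acts$a0 * 0.2
  stepped <- fits[c("model", "noise", "w", "a0", "a1")]
  set.seed(122)
  stepped$er <- stats::runif(nrow(stepped))
  stepped$valid <- TRUE
  gs <- generalize(fits, acts, "MNWS", stepped_results = stepped)
  for (nz in c("none", "balanced")) for (w in c(100, 300)) {
    sub <- stepped[stepped$noise == nz & stepped$w == w, ]
    best <- select_optimal(sub)
    m <- generalized_ln_model(gs, "A", nz, w)
    row <- fits[fits$noise == nz & fits$w == w & fits$a0 == best$a0 &
                  fits$a1 == best$a1, ]
    expect_equal(m$filter$gamma1, row$gamma1)
  }
  expect_error(generalize(fits, acts, "MNWS"), "stepped_results")
})

test_that("k-means grouping recovers separable parameter clouds deterministically", {
  set.seed(123)
  n <- 40
  cloud <- function(model, g1, fc1) {
    data.frame(model = model,
               gamma1 = g1 + stats::rnorm(n, 0, 0.05),
               gamma2 = 0.5 + stats::rnorm(n, 0, 0.05),
               f_c1 = fc1 * exp(stats::rnorm(n, 0, 0.02)),
               f_c2 = 200 * exp(stats::rnorm(n, 0, 0.02)),
               delta = 1 + stats::rnorm(n, 0, 0.02))
  }
  fits <- rbind(cloud("A", -5, 5), cloud("B", -5, 5), cloud("C", 5, 100))
  cl <- cluster_models(fits, k = 2, n_init = 20, seed = 9)
  expect_equal(nrow(cl$groups), 2L)
  expect_equal(cl$assignment[["A"]], cl$assignment[["B"]])
  expect_false(cl$assignment[["A"]] == cl$assignment[["C"]])
  # count matrix conservation: row sums equal fits per model
  expect_equal(unname(rowSums(cl$counts)), c(n, n, n))
  # determinism
  cl2 <- cluster_models(fits, k = 2, n_init = 20, seed = 9)
  expect_identical(cl$assignment, cl2$assignment)
  # all rows identical: a single occupied cluster, no error
  same <- fits
  same[c("gamma1", "gamma2", "f_c1", "f_c2", "delta")] <-
    list(1, 0.5, 10, 100, 1)
  cls <- cluster_models(same, k = 7, n_init = 5, seed = 2)
  expect_equal(nrow(cls$groups), 1L)
  expect_error(cluster_models(fits[1:3, ], k = 7), "at least k")
})

test_that("a surrogate spiking model reproducing an LN prediction scores near-perfect Er", {
  g <- activation_function(seq(0, 400, 50), 0.8 * seq(0, 400, 50))
  m <- ln_model(g, filter_params(1, -0.5, 10, 100, 1),
                provenance = list(a0 = 200, a1 = 100))
  sur <- make_ln_surrogate(m)
  recs <- stepped_poisson_test(sur, list(m), noise_preset("none", "amat"),
                               w = 0, n_neurons = 512, n_seeds = 2,
                               seed = 130)
  expect_true(recs$valid[1])
  expect_gte(recs$er[1], 0.95)
  expect_equal(recs$n_seeds_used[1], 2L)
  # defaults match the full protocol
  expect_equal(eval(formals(stepped_poisson_test)$n_neurons), 4096)
  expect_equal(eval(formals(stepped_poisson_test)$n_seeds), 5)
  # an unresponsive model yields a missing record, not an exception
  dead <- rate_surrogate_spec(function(rb, dt) rep(0, length(rb)))
  recs0 <- stepped_poisson_test(dead, list(m), noise_preset("none", "amat"),
                                w = 0, n_neurons = 8, n_seeds = 2, seed = 131)
  expect_false(recs0$valid[1])
  expect_true(is.na(recs0$er[1]))
})
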