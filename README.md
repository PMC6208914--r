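# lnspike

Reduces spiking neuron models to linear–nonlinear (LN) firing-rate models.

Rate-based network models need a quantitative stand-in for the response of a
spiking neuron to its synaptic input. `lnspike` builds that stand-in for two
widely used model classes — the **Izhikevich** model (two-variable quadratic
dynamics with hard reset, 14 study variants) and the **augmented
multi-adaptive-threshold (AMAT)** model (linear subthreshold dynamics with a
two-timescale adaptive threshold plus a voltage-coupled component, 18 study
variants) — by simulating their spike responses to Poisson input and fitting
an LN cascade to the measured responses. It is aimed at computational
neuroscientists who want calibrated rate models, and at anyone who needs the
ingredients: grid-based Poisson stimulus generators, fixed-kernel spike-rate
estimation, harmonic response analysis, and constrained filter fitting.

## The model

The deliverable is the LN rate model

    r(t) = max(0, g((h * a)(t)))

where `a(t)` is the input rate, `g` is the **activation function** measured
as the stationary response `r0 = g(a0)` on a 101-knot grid (linear B-spline),
and `h(t)` is a normalized causal kernel obtained by fitting the empirical
transfer function `H0(f) = (r1(f)/a1) e^{i phi(f)}` — measured from responses
to sinusoidally modulated Poisson input at 28 frequencies (1–1000 Hz) — with a
**bandpass filter in sum form**

    H(f) = gamma1 e^{-2 pi i f Delta} [ 1/(1 + i f/f_c1) + gamma2/(1 + i f/f_c2) ]

subject to 0.909 Hz ≤ f_c1 ≤ f_c2 ≤ 636.6 Hz (time constants 0.25–175 ms) and
0 ≤ Delta ≤ 75 ms. Because the kernel is a sum of two exponentials, the model
has an equivalent local-in-time ODE form (linear chain trick), provided by
`predict_ode()` alongside the convolution form `predict_convolution()`.
Model quality is scored against the spiking response with
`Er = 1/(1 + normalized MSE)` (1 = perfect, 1/2 = error equal to the response
variance), using a stepped-Poisson test stimulus (100/200/40/150 s⁻¹) and
synthetic retinal-ganglion-cell-like spike trains; fitted kernels are grouped
across variants by k-means on their parameters.

## Worked example

Reduce the AMAT tonic-spiking variant under balanced background noise
(`mu = 0`, `sigma = 100` pA) at synaptic weight 500 pA:

```r
library(lnspike)
spec  <- model_spec("amat", "A")
noise <- noise_preset("balanced", "amat")

# stationary activation function (reduced grid for the example)
g <- measure_activation_function(spec, noise, w = 500,
                                 a0_grid = seq(0, 400, by = 50),
                                 duration = 5000, seed = 1)
round(g$r0, 1)
#> [1]  2.8  8.4 17.0 26.6 45.2 51.8 64.8 78.4 92.6

# transfer function at working point a0 = 200, a1 = 100 s^-1, and its fit
tf <- measure_transfer_function(spec, noise, w = 500, a0 = 200, a1 = 100,
                                n_trials = 64, seed = 2)
ft <- fit_filter(tf, seed = 3)
ft$params
#> <filter_params> gamma1=0.2162 gamma2=0.1264 f_c1=136 Hz f_c2=636.6 Hz delta=0 ms

# LN model, scored on the stepped-Poisson test stimulus
m <- ln_model(g, ft$params, provenance = list(a0 = 200, a1 = 100))
recs <- stepped_poisson_test(spec, list(m), noise, w = 500,
                             n_neurons = 512, n_seeds = 2, seed = 4)
recs$er
#> [1] 0.9230684
```

The activation knots are the measured stationary rates (s⁻¹); the fitted
filter is mildly bandpass (`gamma2 > 0`, upper characteristic frequency at
the bound); `Er = 0.92` means the LN prediction captures the population rate
response to rate steps to well within its variance. `run_ln_pipeline()`
chains these steps over a working-point grid and selects the best fit;
`generalize()` pools fits to per-model/per-noise/per-weight generalizations;
`cluster_models()` groups variants by their fitted kernels.

A thin command-line wrapper over the same functions is installed at
`inst/exec/lnspike` (subcommands `simulate`, `activation`, `transfer`, `fit`,
`predict`, `stepped-test`, `rgc-test`, `generalize`, `cluster`, `synth-rgc`);
see `lnspike::cli("--help")`.

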