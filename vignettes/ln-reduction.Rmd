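---
title: "Reducing spiking neuron models to linear-nonlinear rate models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing spiking neuron models to linear-nonlinear rate models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lnspike)
```

This vignette documents the models, conventions and numerical choices behind
`lnspike`. It is the place where every decision that was genuinely open is
recorded, together with its rationale.

## The two spiking model classes

**Izhikevich class.** Two variables, membrane potential `v` (mV) and recovery
`u`, with quadratic dynamics

    v' = 0.04 v^2 + 5 v + 140 - u + I,     u' = a (b v - u)

and a hard reset `v <- c`, `u <- u + d` whenever `v >= 30` mV. All quantities
except time and `v` are treated as unitless, following the original
parameterization (input "currents" carry the exotic unit mV/ms). The study
set comprises the 14 variants whose published parameters are distinct and
whose dynamics follow these canonical equations; variants based on modified
equations or duplicate parameter sets (G, I, L, O, R) and the one that is
unstable on a sub-millisecond grid (T) are excluded but still shipped in the
parameter file. Integration is forward Euler on the fixed `dt = 0.1` ms grid,
with a single membrane update per step by default; `substeps` reproduces the
historical scheme (1 ms steps with two 0.5 ms membrane substeps) when wanted.
The recovery variable is updated once per step from the already-updated `v`,
as in the published source code of the model. Input spikes jump `v`
instantaneously; their weights are expressed as fractions of the per-variant
weight factor `xi`, the smallest jump that triggers the spike initiation
process from rest. (Note that the printed `xi` values are rounded; for the
tonic-spiking variant the numerical initiation boundary from rest lies about
0.5% above the printed 15.1, so tests that require a triggered spike use a
5% margin.)

**AMAT class.** A leaky integrator with linear subthreshold dynamics
(`tau_m = 10` ms, `C_m = 200` pF, `E_L = -70` mV), exponential synaptic
currents (`tau_syn,E = 1` ms for positive weights, `tau_syn,I = 3` ms for
negative ones), and *no reset*: spiking is controlled by an adaptive
threshold

    theta(t) = omega + th_1(t) + th_2(t) + th_v(t)

where `th_1`, `th_2` jump by `alpha_1`, `alpha_2` (mV) at every output spike
and decay with `tau_1 = 10` ms and `tau_2 = 200` ms, and the "augmented"
component `th_v` couples to the membrane potential. The exact published form
of the augmented component was not available to us; we implement it as the
simplest linear state consistent with its description — a first-order
low-pass of the membrane-potential deviation with gain `beta` and time
constant `tau_V = 5` ms,

    tau_V th_v' = -th_v + beta (V - E_L),

updated by exponential Euler with the start-of-step potential. With
`beta = 0` this degenerates exactly to the plain two-timescale adaptive
threshold, which is asserted in the tests. Subthreshold integration uses
exact propagators (the system is linear), so the voltage trace equals the
analytic superposition of postsynaptic potentials to machine precision.

**Refractoriness.** After an output spike the AMAT neuron cannot fire for
`tau_ref = 2` ms; the implementation allows the next spike exactly
`tau_ref` after the last one, so the saturation ceiling under overwhelming
drive is exactly `1/tau_ref = 500` spikes/s. We chose this convention (rather
than `tau_ref + dt`) because the 500 s⁻¹ ceiling is the documented behaviour
of the class; the inter-spike-interval invariant `ISI >= tau_ref` holds with
equality at saturation.

**Grid conventions.** Step `n` covers `((n-1) dt, n dt]`. Input spike times
are floored to the grid (with a 1e-6-bin tolerance so that intended grid
multiples survive floating-point division); several spikes in one step sum
their weights. An output spike emitted during a step is stamped at the
step's *start* time, which keeps all spike times inside the half-open
recording window and makes spike counts exactly invariant under splitting a
run into two with carried-over state. These half-step conventions shift
measured response phases by at most one grid step; the fitted delay
parameter absorbs them.

**Background noise.** Three regimes are used throughout: none; balanced
(`mu = 0`, `sigma = 0.1` unitless for Izhikevich / 100 pA for AMAT); biased
(`mu = -0.1`/`-100` pA, `sigma = 0.2`/200 pA). For the Izhikevich class the
noise is an approximate Gaussian white-noise current redrawn independently
every step with the *given* standard deviation — deliberately without
`1/sqrt(dt)` scaling, because the published sigma values are tied to that
generator convention; the effective diffusion therefore depends on `dt`,
which is documented rather than "fixed". For the AMAT class the noise is
delivered as excitatory and inhibitory Poisson event trains with fixed
weights `w_E = 1` pA and `w_I = -4/3` pA; `solve_background_rates()` inverts
the shot-noise mean/variance equations for the event rates (for balanced
noise this gives `nu_E = 4 nu_I`, several megahertz because the weights are
tiny).

## Stimuli

All Poisson generators use the grid dialect: one Bernoulli draw per
`dt = 0.1` ms bin with `p = a(t) dt`, `a` evaluated at the bin centre, and
the spike stamped at the bin start. An exact time-rescaling alternative is
available for cross-checks (`method = "rescaling"`). Modulation depth is
constrained to `a1 <= a0` so the intensity never rectifies.

The synthetic retinal-ganglion-cell-like generator emulates only the summary
statistics of the recordings it stands in for: 96 trains of 8 s with a
grand-mean rate of 18.3 s⁻¹, low baseline and fast transients. Its rate
profile is a constant baseline (default 8 s⁻¹) plus 12 Gaussian transients
(sd 15 ms) at fixed irregular preset times, with the transient amplitude
calibrated in closed form so the *expected* mean rate equals the target
(182.6 s⁻¹ at the defaults). Everything else about the real data — its
trial-to-trial correlations, refractoriness, precise transient shapes and
any slow nonstationarity — is *not* emulated, so tests that pass on these
trains demonstrate correct plumbing and calibration, not fidelity to real
retinal dynamics. Pairwise merging (`merge_train_pairs()`) halves the count
to 48 trains and doubles the mean rate.

## Response characterization

**Rate estimation** uses fixed-kernel Gaussian smoothing on a 0.05 ms grid
with the kernel width selected by minimizing the cross-validation cost
`C(w) = sum_{ij} k_{w sqrt 2}(x_i - x_j) - 2 sum_{i != j} k_w(x_i - x_j)`
over a 40-point logarithmic width grid (0.2–200 ms); pair sums are computed
from the FFT autocorrelation of the binned counts, which is exactly the
brute-force pairwise sum for binned spike times. Estimates whose optimal
width exceeds 15 ms are flagged invalid and discarded by the scoring
functions, since wider kernels smooth away the transients being scored. Edge
effects are not corrected; with widths ≤ 15 ms on ≥ 1.5 s windows the mass
loss is far below the 1% integral-conservation tolerance asserted in the
tests.

**Harmonic analysis** fits the periodically driven response with
`r(t) = r0 + sum_m r_m cos(2 pi m f t + phi_m)`, reading `r_m`, `phi_m` from
the FFT of the pooled PSTH over an integer number of periods. A harmonic is
significant at the 99% level when `r_m > r_crit = B + 2.34 Sigma`, with the
background level `B` and spread `Sigma` estimated from the non-harmonic bins
within ±25% of `f` around the harmonic (at least 12 bins per side). The
exact background convention of the original analysis was not available; we
evaluated two: weighting the background bins by inverse distance to the
harmonic concentrates `Sigma` on very few bins and inflates the
false-positive rate of the criterion to ~6%, while uniform weighting keeps
it at the ~2% implied by the amplitude statistics of Poisson noise. Uniform
weighting is therefore the default (`bg_weighting` switches back).

**Activation functions** are measured at 101 stationary input rates
(0–1000 s⁻¹ in steps of 10) for 10 s per knot after 1 s equilibration
(≤ 2% standard error at 100 s⁻¹), and represented as a linear B-spline that
interpolates the knots exactly and extrapolates linearly. The linearity
score `L1 = 1/(1 + Lbar1)` uses the continuous least-squares line computed
by trapezoidal quadrature on a 4001-point grid; if the best line vanishes at
the interval midpoint the normalization is undefined and a flagged `NA` is
returned.

## Transfer functions and filter fits

Transfer functions are measured at 28 log-spaced frequencies (1–1000 Hz).
Each recording spans an integer number of stimulus periods — at least 8, and
at least 1 s — so every harmonic falls exactly on a DFT bin; the stimulus
frequency is snapped to the grid (relative shift < 1e-5) and the snapped
value is used for both stimulation and analysis. The phase convention makes
a memoryless positive gain real and positive, matching the filter formula.
A frequency point is valid when its first harmonic is significant; a
condition with no valid point and mean rate < 1 s⁻¹ is flagged missing
(insufficient spiking), mirroring the sweep conditions for which no kernel
can be fitted.

The bandpass filter is fitted by minimizing the summed squared modulus of
the complex residuals (amplitude and phase jointly; an amplitude-only option
exists for sensitivity checks) over `(gamma1, gamma2, f_c1, f_c2, Delta)`
with L-BFGS-B within the bounds `tau_c in [0.25, 175]` ms
(`f_c in [0.909, 636.6]` Hz) and `Delta in [0, 75]` ms, from 60 random
starts (characteristic frequencies log-uniform, `gamma2` uniform in (-3, 3),
the linear gain solved in closed form per start). A pure lowpass is fitted
from 15 starts for comparison, and one additional bandpass start is seeded
at the lowpass optimum, which guarantees the reported bandpass loss never
exceeds the lowpass loss. If a fit ends with `f_c1 > f_c2` the branches are
relabelled (`gamma1 <- gamma1 gamma2`, `gamma2 <- 1/gamma2`), which leaves
the filter unchanged. With almost-coincident poles the parameterization is
sloppy — individual gains are then not identifiable even from noiseless
data, although the filter shape is recovered; tests assert parameter
recovery only for identifiable targets and shape recovery in the degenerate
regime.

## LN prediction

The kernel is normalized to unit integral, so stationary input reproduces
the activation function exactly; `gamma1` is absorbed by the activation
function and does not enter the prediction. `predict_convolution()` uses the
*bin-integrated* kernel (exact integrals of `h` over grid bins), which makes
discrete convolution of a piecewise-constant input the exact linear
response; `predict_ode()` integrates the equivalent two-variable linear
chain with exact exponential-integrator steps and a delay buffer. The two
paths are mathematically identical for piecewise-constant input and agree to
numerical precision, which the tests exploit as a cross-check (including the
near-singular normalization `gamma2 -> -1`; the constructor rejects
`|1 + gamma2| <= 1e-12`). The delay is snapped to the prediction grid.
Rectification (`max(0, .)`) exists only to guard against negative rates from
extrapolating the activation spline. Predictions can start from the
stationary state of the initial input value (used when the spiking
population was equilibrated at that rate) or from zero.

## Scoring, selection, generalization, grouping

`Er = 1/(1 + Ebar)` with `Ebar` the mean squared prediction error normalized
by the variance of the spiking response, integrated by the rectangle rule on
the common 0.05 ms grid. The stepped-Poisson test equilibrates the
population at the schedule's first rate (1 s), so predictions start from the
matching fixed point; by default the first `Delta + 3 tau_2` ms are excluded
from the score as kernel warm-up (`exclude_transient = FALSE` integrates
from 0, the behaviour assumed by the original analysis). Scores are averaged
over the seeds whose KDE width passed the 15 ms validity rule; conditions
with no usable seed yield missing records. The optimal model per condition
is the working-point argmax of `Er`.

Generalizations pool the per-condition fits at four levels (M, MN, MNW,
MNWS). For M and MN the activation data are pooled as `g(a)/w` and refitted
as a single scaled spline (knot-wise means, which is the least-squares
linear spline when all conditions share the knot grid); kernel parameters
are per-parameter medians (robust to outliers); MNWS instead selects the
single working point with the best stepped-test score. Model grouping runs
k-means (`k = 7`, 100 random initializations) on the z-scored parameter
vectors with the characteristic frequencies on a log scale — the feature
preparation of the original analysis was not available, so the scaling is
exposed as options; plurality ties are broken toward the larger cluster,
then the lower index, for determinism. If fewer distinct parameter sets than
clusters exist, the distinct sets are clustered directly (identical fits
share a cluster) rather than failing.

## Problem sizes used by the test suite

The full protocol (20 working points, 1024 trials per frequency, 4096
neurons, 5 seeds, 60 fit starts) is available throughout and is what
`scripts/full_sweep.R` runs. The package's own end-to-end check runs a
deliberately scaled-down sweep chosen to exercise every stage while staying
desk-sized: variants A, C, Q of both classes, all three noise regimes, two
mid/strong weights per class (0.25/0.6 of `xi`; 300/700 pA), six working
points (`a0 in {100, 200, 400}`, `a1 in {0.5, 1} a0`), 16 trials per
frequency, 10 fit starts, 512 neurons and 2 stepped-test seeds, with 8 s
activation measurements. At this scale the transfer-function estimates are
noisier and weakly responding conditions (notably the Izhikevich class at
the lower weight) drop out as missing, as they do at full scale; the
directional comparison between the classes is robust to this, the absolute
percentages are not — reproducing those requires the full sweep.

## Known limitations

* The augmented-threshold form is a faithful implementation of a documented
  *description*, not of withheld source; variants with large `|beta|` are
  the most sensitive to this choice.
* Second-harmonic structure is measured but never fitted; the bandpass
  family cannot represent resonance peaks caused by refractory regularity at
  high rates, and inherits all limitations of linearization around a working
  point.
* The synthetic RGC-like trains match summary statistics only (see above).
* KDE edge effects are uncorrected; spectral estimates assume
  integer-period windows and will refuse anything else.
* Phase estimates carry up to one-grid-step convention latency, absorbed by
  the fitted delay.
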