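#include <Rcpp.h>
using namespace Rcpp;

// Core integrators for the two spiking model classes. Both operate on a fixed
// time grid of width dt; step n covers (n*dt, (n+1)*dt] and state reported for
// step n is the state at time (n+1)*dt. Output spikes are reported as 1-based
// step indices so that spike times are idx*dt.
//
// Stochastic inputs drawn inside the kernels use R's RNG (unif_rand, norm_rand,
// R::rpois), so results are reproducible via set.seed() on the R side. Draw
// order per step is fixed and documented below.

// Izhikevich model class, forward Euler on the canonical two-variable form
//   v' = 0.04 v^2 + 5 v + 140 - u + I,  u' = a (b v - u)
// with reset v <- c, u <- u + d when v >= v_th after the update. Input spikes
// add their weight to v instantaneously at the start of the step in which they
// arrive. The membrane update may be split into `substeps` sub-iterations (the
// recovery variable is always updated once per step, from the updated v, as in
// the original published code).
//
// Per-step order: (1) draw Bernoulli stimulus spike if input_p given (one
// unif_rand when input_p[n] > 0), (2) add explicit jump, (3) draw Gaussian
// noise term if enabled (one norm_rand), (4) substepped v update, (5) u update,
// (6) threshold test / reset.
// [[Rcpp::export]]
List izhikevich_kernel(double a, double b, double c, double d,
                       double v_th, double i_ext,
                       NumericVector current,
                       NumericVector input_jump,
                       NumericVector input_p, double w_jump,
                       double noise_mu, double noise_sigma, bool use_noise,
                       double v0, double u0,
                       double dt, int n_steps, int substeps, bool record) {
  double v = v0, u = u0;
  std::vector<int> spikes;
  NumericVector vtr(record ? n_steps : 0), utr(record ? n_steps : 0);
  const bool has_cur = current.size() > 0;
  const bool has_jump = input_jump.size() > 0;
  const bool has_p = input_p.size() > 0;
  const double h = dt / substeps;
  for (int n = 0; n < n_steps; ++n) {
    double I = i_ext;
    if (has_cur) I += current[n];
    if (has_p && input_p[n] > 0.0) {
      if (unif_rand() < input_p[n]) v += w_jump;
    }
    if (has_jump) v += input_jump[n];
    if (use_noise) I += noise_mu + noise_sigma * norm_rand();
    for (int s = 0; s < substeps; ++s)
      v = v + h * (0.04 * v * v + 5.0 * v + 140.0 - u + I);
    u = u + dt * (a * (b * v - u));
    if (!R_finite(v) || !R_finite(u))
      stop("Izhikevich state diverged at t = " +
           std::to_string((n + 1) * dt) + " ms");
    if (v >= v_th) {
      spikes.push_back(n + 1);
      v = c;
      u = u + d;
    }
    if (record) { vtr[n] = v; utr[n] = u; }
  }
  return List::create(_["spike_steps"] = wrap(spikes),
                      _["v"] = v, _["u"] = u,
                      _["v_trace"] = vtr, _["u_trace"] = utr);
}

// AMAT model class: linear subthreshold dynamics advanced by exact-integration
// propagators, exponentially decaying synaptic currents, multi-timescale
// adaptive threshold with a voltage-dependent ("augmented") component, no
// membrane reset at spikes.
//
//   tau_m V' = -(V - E_L) + (tau_m/C_m) (I_E + I_I + I_ext)
//   tau_X I_X' = -I_X                   (X = E, I; spikes add their weight)
//   theta(t) = omega + th1 + th2 + th_v
//   th1' = -th1/tau_1, th2' = -th2/tau_2 (spike: th1 += alpha1, th2 += alpha2)
//   tau_V th_v' = -th_v + beta (V - E_L) (exponential-Euler, start-of-step V)
//
// A spike is emitted at the end of a step when V >= theta and at least tau_ref
// has elapsed since the previous spike (minimal ISI is exactly tau_ref).
//
// Per-step draw order: stimulus Bernoulli (unif_rand, only when input_p[n]>0),
// excitatory background count (rpois), inhibitory background count (rpois).
// [[Rcpp::export]]
List amat_kernel(double alpha1, double alpha2, double beta,
                 double e_l, double omega, double c_m,
                 double tau_m, double tau_1, double tau_2, double tau_v,
                 double tau_ref, double tau_e, double tau_i,
                 NumericVector current,
                 NumericVector d_ie, NumericVector d_ii,
                 NumericVector input_p, double w_stim,
                 double nu_e_bin, double nu_i_bin,
                 double w_e_bg, double w_i_bg, bool use_bg,
                 double v0, double ie0, double ii0,
                 double th10, double th20, double thv0, int ref0,
                 double dt, int n_steps, bool record) {
  const double pm = std::exp(-dt / tau_m);
  const double pe = std::exp(-dt / tau_e);
  const double pi = std::exp(-dt / tau_i);
  const double p1 = std::exp(-dt / tau_1);
  const double p2 = std::exp(-dt / tau_2);
  const double pv = std::exp(-dt / tau_v);
  // exact propagator: contribution of a synaptic current of amplitude 1 at the
  // start of the step to V at the end of the step
  const double pve = (std::exp(-dt / tau_e) - std::exp(-dt / tau_m)) /
                     ((1.0 / tau_m - 1.0 / tau_e) * c_m);
  const double pvi = (std::exp(-dt / tau_i) - std::exp(-dt / tau_m)) /
                     ((1.0 / tau_m - 1.0 / tau_i) * c_m);
  const double pvc = tau_m / c_m * (1.0 - pm);  // constant current over step
  const int ref_steps = (int)std::lround(tau_ref / dt);

  double v = v0, ie = ie0, ii = ii0;
  double th1 = th10, th2 = th20, thv = thv0;
  int ref = ref0;
  std::vector<int> spikes;
  NumericVector vtr(record ? n_steps : 0), thtr(record ? n_steps : 0);
  const bool has_cur = current.size() > 0;
  const bool has_ie = d_ie.size() > 0;
  const bool has_ii = d_ii.size() > 0;
  const bool has_p = input_p.size() > 0;

  for (int n = 0; n < n_steps; ++n) {
    if (has_p && input_p[n] > 0.0) {
      if (unif_rand() < input_p[n]) ie += w_stim;
    }
    if (use_bg) {
      if (nu_e_bin > 0.0) ie += w_e_bg * R::rpois(nu_e_bin);
      if (nu_i_bin > 0.0) ii += w_i_bg * R::rpois(nu_i_bin);
    }
    if (has_ie) ie += d_ie[n];
    if (has_ii) ii += d_ii[n];
    const double v_prev = v;
    double i_ext_n = has_cur ? current[n] : 0.0;
    v = e_l + (v - e_l) * pm + ie * pve + ii * pvi + i_ext_n * pvc;
    ie *= pe;
    ii *= pi;
    thv = thv * pv + beta * (v_prev - e_l) * (1.0 - pv);
    th1 *= p1;
    th2 *= p2;
    if (!R_finite(v))
      stop("AMAT state diverged at t = " + std::to_string((n + 1) * dt) +
           " ms");
    if (ref > 0) --ref;
    if (ref == 0 && v >= omega + th1 + th2 + thv) {
      spikes.push_back(n + 1);
      th1 += alpha1;
      th2 += alpha2;
      ref = ref_steps;
    }
    if (record) { vtr[n] = v; thtr[n] = omega + th1 + th2 + thv; }
  }
  return List::create(_["spike_steps"] = wrap(spikes),
                      _["v"] = v, _["ie"] = ie, _["ii"] = ii,
                      _["th1"] = th1, _["th2"] = th2, _["thv"] = thv,
                      _["ref"] = ref,
                      _["v_trace"] = vtr, _["theta_trace"] = thtr);
}

// Bernoulli thinning of a per-bin spike probability vector; returns 0-based
// bin indices. One unif_rand per bin with p > 0 (same draw order as the
// in-kernel generators above).
// [[Rcpp::export]]
IntegerVector bernoulli_bins(NumericVector p) {
  std::vector<int> hits;
  const int n = p.size();
  for (int i = 0; i < n; ++i) {
    if (p[i] > 0.0 && unif_rand() < p[i]) hits.push_back(i);
  }
  return wrap(hits);
}
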