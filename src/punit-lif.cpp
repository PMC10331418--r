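#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the adapting leaky integrate-and-fire
// P-unit model with dendritic low-pass prefilter.
//
// All time constants are in ms; the integration step is dt = 1000/rate ms.
// The stimulus is rectified and exponentiated (max(x,0)^p) before driving
// the dendritic compartment. Noise: Gaussian increment of variance 2*D*dt
// added to the numerator of the membrane update (D in ms, voltages
// dimensionless). On a spike the membrane is reset to 0, clamped there for
// t_ref, and the adaptation variable jumps by delta_a/tau_a.
//
// A cyclic warm-up of n_warm samples (stimulus indices wrap) lets the
// adaptation settle; warm-up spikes are discarded.
//
// [[Rcpp::export]]
NumericVector punit_lif_cpp(NumericVector stimulus, double rate,
                            double beta, double tau_m, double mu,
                            double noise_d, double tau_a, double delta_a,
                            double tau_d, double t_ref, double p,
                            double delta_v, bool eif, int n_warm) {
  const int n = stimulus.size();
  const double dt = 1000.0 / rate;              // ms
  const double sq = std::sqrt(2.0 * noise_d * dt);
  const double thresh = eif ? 1.0 + 10.0 * delta_v : 1.0;
  const bool pow1 = (p == 1.0);

  double v = 0.0, vd = 0.0, a = 0.0, ref = 0.0;
  std::vector<double> spikes;
  spikes.reserve(static_cast<size_t>(n * dt));  // ~1 spike per ms at most

  for (int i = -n_warm; i < n; ++i) {
    int j = i >= 0 ? i : ((i % n) + n) % n;
    double s = stimulus[j];
    s = s > 0.0 ? (pow1 ? s : std::pow(s, p)) : 0.0;

    vd += (-vd + s) * dt / tau_d;
    if (ref > 0.0) {
      ref -= dt;
      v = 0.0;
    } else {
      double f = eif ? delta_v * std::exp((v - 1.0) / delta_v) : 0.0;
      double drift = (-v + f + mu + beta * vd - a) * dt;
      double noise = noise_d > 0.0 ? sq * norm_rand() : 0.0;
      v += (drift + noise) / tau_m;
    }
    a -= a * dt / tau_a;

    if (!std::isfinite(v))
      stop("membrane voltage diverged (unstable time step or parameters)");

    if (ref <= 0.0 && v >= thresh) {
      v = 0.0;
      a += delta_a / tau_a;
      ref = t_ref;
      if (i >= 0) spikes.push_back(i / rate);
    }
  }
  return wrap(spikes);
}
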