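#include <Rcpp.h>
using namespace Rcpp;

// Fast normal deviates: xoshiro256++ uniforms + Marsaglia polar transform.
// The generator is seeded from R's RNG at every epoch call, so set.seed()
// still controls the simulation exactly; R's own normal generator is an
// inversion of qnorm and is several times slower at the 1e8+ draws an
// epoch needs.
namespace {
struct FastNormal {
  uint64_t s[4];
  double spare;
  bool has_spare;
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit FastNormal(uint64_t seed) : has_spare(false) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
    spare = 0.0;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next_u64() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double next_unif() { // in (-1, 1)
    return (double)(int64_t)next_u64() * (1.0 / 9223372036854775808.0);
  }
  inline double next_norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, r2;
    do {
      u = next_unif(); v = next_unif();
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};
} // namespace

// Euler integration of the all-to-all LIF network with NMDA/AMPA/GABA
// current channels. The recurrent input to a neuron depends on presynaptic
// spikes only through per-population spike counts (block-structured
// efficacies), so each step costs O(N + n_pops^2) rather than O(N^2).
//
// Conventions (documented in the package vignette):
//  - spikes emitted in a step are delivered as current kicks at the end of
//    that step (one-step transmission delay of dt);
//  - no self-connections: a spiking neuron's own block contribution is
//    subtracted from its kick;
//  - refractory neurons are clamped at V_R and do not consume noise draws;
//    their synaptic currents keep integrating;
//  - fast noise enters as independent Gaussian increments of SD
//    sigma * sqrt(dt / tau_m), from the FastNormal generator above whose
//    seed the caller derives from R's RNG (so set.seed() still governs).
//
// [[Rcpp::export]]
List spiking_run_epoch_cpp(NumericVector V_in, NumericVector IN_in,
                           NumericVector IA_in, NumericVector IG_in,
                           NumericVector refr_in, double t0,
                           IntegerVector pop, // 1-based population index
                           NumericVector mu,  // per-neuron mean drive (mV)
                           NumericMatrix Jblock, // J[post_pop, pre_pop] (mV)
                           LogicalVector pop_is_inhib,
                           NumericVector pop_tau_m, NumericVector pop_X,
                           double tau_N, double tau_A, double tau_G,
                           double theta, double V_R, double tau_arp,
                           double sigma, double dt, int n_steps,
                           int bin_steps, bool record_spikes,
                           double noise_seed) {
  const int n = V_in.size();
  const int n_pops = Jblock.nrow();
  NumericVector V = clone(V_in), IN = clone(IN_in), IA = clone(IA_in),
                IG = clone(IG_in), refr = clone(refr_in);

  // per-population integration coefficients
  std::vector<double> a_m(n_pops), noise_sd(n_pops), kickN(n_pops),
      kickA(n_pops), kickG(n_pops);
  for (int q = 0; q < n_pops; ++q) {
    a_m[q] = dt / pop_tau_m[q];
    noise_sd[q] = sigma * std::sqrt(dt / pop_tau_m[q]);
    kickN[q] = pop_X[q] * pop_tau_m[q] / tau_N;
    kickA[q] = (1.0 - pop_X[q]) * pop_tau_m[q] / tau_A;
    kickG[q] = pop_tau_m[q] / tau_G;
  }
  const double dN = dt / tau_N, dA = dt / tau_A, dG = dt / tau_G;

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<int> count(n_pops);
  std::vector<double> sumE(n_pops), sumI(n_pops);
  std::vector<int> spiked;
  spiked.reserve(256);

  const int n_bins = (n_steps + bin_steps - 1) / bin_steps;
  IntegerMatrix bin_counts(n_bins, n_pops);

  FastNormal rng((uint64_t)(noise_seed * 4294967296.0) + 0x1234567ULL);
  for (int step = 0; step < n_steps; ++step) {
    const double t = t0 + step * dt;
    const double t_spike = t + dt;
    std::fill(count.begin(), count.end(), 0);
    spiked.clear();
    const int bin = step / bin_steps;
    for (int i = 0; i < n; ++i) {
      const int q = pop[i] - 1;
      // synaptic currents integrate regardless of refractoriness
      IN[i] -= dN * IN[i];
      IA[i] -= dA * IA[i];
      IG[i] -= dG * IG[i];
      if (t < refr[i] - 1e-12) {
        V[i] = V_R;
        continue;
      }
      const double Itot = mu[i] + IN[i] + IA[i] - IG[i];
      V[i] += a_m[q] * (Itot - V[i]) + noise_sd[q] * rng.next_norm();
      if (V[i] >= theta) {
        V[i] = V_R;
        refr[i] = t_spike + tau_arp;
        ++count[q];
        spiked.push_back(i);
        bin_counts(bin, q) += 1;
        if (record_spikes) {
          spike_t.push_back(t_spike);
          spike_id.push_back(i + 1);
        }
      }
      if (!R_finite(V[i]))
        stop("non-finite membrane potential at t = %f s (neuron %d)", t, i + 1);
    }
    // block-summed recurrent kicks from this step's spikes
    bool any_spike = false;
    for (int q = 0; q < n_pops; ++q)
      if (count[q] > 0) { any_spike = true; break; }
    if (!any_spike) continue;
    for (int qpost = 0; qpost < n_pops; ++qpost) {
      double sE = 0.0, sI = 0.0;
      for (int qpre = 0; qpre < n_pops; ++qpre) {
        if (count[qpre] == 0) continue;
        const double w = Jblock(qpost, qpre) * count[qpre];
        if (pop_is_inhib[qpre]) sI += w; else sE += w;
      }
      sumE[qpost] = sE;
      sumI[qpost] = sI;
    }
    for (int i = 0; i < n; ++i) {
      const int q = pop[i] - 1;
      if (sumE[q] != 0.0) {
        IN[i] += kickN[q] * sumE[q];
        IA[i] += kickA[q] * sumE[q];
      }
      if (sumI[q] != 0.0) IG[i] += kickG[q] * sumI[q];
    }
    // remove self-connection contribution for neurons that spiked
    for (size_t k = 0; k < spiked.size(); ++k) {
      const int i = spiked[k];
      const int q = pop[i] - 1;
      const double Jself = Jblock(q, q);
      if (Jself == 0.0) continue;
      if (pop_is_inhib[q]) {
        IG[i] -= kickG[q] * Jself;
      } else {
        IN[i] -= kickN[q] * Jself;
        IA[i] -= kickA[q] * Jself;
      }
    }
  }

  return List::create(
      _["V"] = V, _["I_N"] = IN, _["I_A"] = IA, _["I_G"] = IG,
      _["refractory_until"] = refr, _["t"] = t0 + n_steps * dt,
      _["spike_times"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_ids"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["bin_counts"] = bin_counts);
}
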