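// Core network simulator: N excitatory LIF neurons + 1 inhibitory WTA neuron,
// alpha-function synapses (two first-order low-pass stages), forward Euler at
// dt, additive exponential STDP (nearest-neighbor or all-to-all presynaptic
// pairing) on feed-forward and lateral synapses, lateral sum normalization.
//
// Noise is generated inside the step loop (per-bin Bernoulli realized as a
// binomial count plus a uniform distinct subset, which is distributionally
// identical), either per neuron (default; only the frozen pattern is shared)
// or fully shared. A self-contained xoshiro256++ stream keeps runs
// reproducible and independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 seeding + xoshiro256++
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  void seed(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Binomial sampler with a precomputed CDF table (p and n fixed per process;
// tail truncated where the CDF is within 1e-15 of one).
struct BinomTable {
  std::vector<double> cdf;
  void init(int n, double p) {
    cdf.clear();
    if (n <= 0 || p <= 0.0) { cdf.push_back(1.0); return; }
    double pmf = std::exp((double)n * std::log1p(-p));
    double c = pmf;
    cdf.push_back(c);
    double odds = p / (1.0 - p);
    for (int k = 0; k < n; ++k) {
      pmf *= odds * (double)(n - k) / (double)(k + 1);
      c += pmf;
      cdf.push_back(c);
      if (c > 1.0 - 1e-15 && k > (int)(n * p)) break;
    }
  }
  inline int draw(Xoshiro &rng) const {
    double u = rng.unif();
    int lo = 0, hi = (int)cdf.size() - 1;
    if (u <= cdf[0]) return 0;
    // binary search: first k with cdf[k] >= u
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  }
};

// ---------------------------------------------------------------------------
// Exponential decay lookup (integer step differences)
// ---------------------------------------------------------------------------

struct DecayTable {
  std::vector<double> tab;
  double dt_over_tau;
  void init(double dt, double tau, int n = 8192) {
    dt_over_tau = dt / tau;
    tab.resize(n);
    for (int i = 0; i < n; ++i) tab[i] = std::exp(-dt_over_tau * i);
  }
  inline double operator()(int d) const {
    if (d < (int)tab.size()) return tab[d];
    return std::exp(-dt_over_tau * d);
  }
};

// ---------------------------------------------------------------------------
// Main simulator
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(int n_exc, int n_aff, int n_pat_aff,
                     int n_steps, double dt,
                     double tau_m, double theta, double theta_inh,
                     double tau_r, double tau_f,
                     IntegerVector pat_aff, IntegerVector pat_bin,
                     IntegerVector pat_start, // per-pattern index into pat_* (len n_patterns+1)
                     IntegerVector pat_dur,   // per-pattern duration in bins
                     IntegerVector sched_onset, IntegerVector sched_pat,
                     double p_carrier, double p_background,
                     bool shared_noise,
                     NumericMatrix w_ff_in, NumericMatrix w_lat_in,
                     double wp_max, double wl_max,
                     double a_p_ff, double a_d_ff,
                     double a_p_lat, double a_d_lat,
                     double tau_p, double tau_d,
                     int stdp_mode,     // 0 = nearest-neighbor, 1 = all-to-all
                     int nn_dep,        // NN depression: 0 = all posts (trace), 1 = nearest post only
                     bool plastic,
                     double lateral_scale,
                     double w_ei, double w_ie,
                     int seed,
                     int snapshot_every, bool snapshot_ff,
                     int v_record_neuron) {
  if (n_exc < 1 || n_aff < 1) stop("need at least one neuron and one afferent");
  if (n_pat_aff > n_aff) stop("n_pat_aff exceeds n_aff");

  const int n_patterns = pat_start.size() - 1;
  const int n_sched = sched_onset.size();
  const int n_noise_aff = n_aff - n_pat_aff;

  // copies we can mutate
  NumericMatrix w_ff = clone(w_ff_in);
  NumericMatrix w_lat = clone(w_lat_in);

  // per-bin spike probabilities
  const double p64 = 1.0 - (1.0 - p_carrier) * (1.0 - p_background);
  const double p10 = p_background;

  // per-pattern, per-relative-bin index into pat_aff
  // starts[p][b] .. starts[p][b+1] are the spikes of pattern p at bin b
  std::vector< std::vector<int> > pstarts(n_patterns);
  for (int p = 0; p < n_patterns; ++p) {
    int lo = pat_start[p], hi = pat_start[p + 1];
    int dur = pat_dur[p];
    pstarts[p].assign(dur + 1, 0);
    for (int i = lo; i < hi; ++i) {
      int b = pat_bin[i];
      if (b < 0 || b >= dur) stop("pattern spike bin out of range");
      pstarts[p][b + 1]++;
    }
    for (int b = 0; b < dur; ++b) pstarts[p][b + 1] += pstarts[p][b];
    // counting sort requires pat_* sorted by bin within each pattern (R side
    // guarantees this); verify monotonicity
    for (int i = lo + 1; i < hi; ++i)
      if (pat_bin[i] < pat_bin[i - 1]) stop("pattern spikes must be sorted by bin");
  }

  // RNG streams: one per excitatory neuron (per-neuron noise) or one shared
  int n_streams = shared_noise ? 1 : n_exc;
  std::vector<Xoshiro> rng(n_streams);
  for (int k = 0; k < n_streams; ++k)
    rng[k].seed((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL * (k + 1));

  BinomTable bt_noise64, bt_pat64, bt_pat10;
  bt_noise64.init(n_noise_aff, p64);
  bt_pat64.init(n_pat_aff, p64);
  bt_pat10.init(n_pat_aff, p10);

  DecayTable Ep, Ed;
  Ep.init(dt, tau_p);
  Ed.init(dt, tau_d);
  const double decay_d_step = std::exp(-dt / tau_d);

  // neuron state
  std::vector<double> V(n_exc, 0.0);
  std::vector<double> Sr_ff(n_exc, 0.0), Sf_ff(n_exc, 0.0);
  std::vector<double> Sr_lat(n_exc, 0.0), Sf_lat(n_exc, 0.0);
  std::vector<double> Sr_inh(n_exc, 0.0), Sf_inh(n_exc, 0.0);
  double Vi = 0.0, Sr_i = 0.0, Sf_i = 0.0;

  // plasticity traces
  std::vector<double> post_trace(n_exc, 0.0);
  size_t n_syn = (size_t)n_aff * n_exc;
  std::vector<double> pre_trace(n_syn, 0.0);
  std::vector<int> pre_last(n_syn, -1);
  std::vector<double> lat_trace(n_exc, 0.0);
  std::vector<int> lat_last(n_exc, -1);
  // nearest-neighbor depression: each post spike pairs only with the nearest
  // pre spike after it. Realized as a post-trace difference: the part of the
  // post trace already seen by the previous pre event on this synapse is
  // subtracted, so each post contributes to exactly one pre event.
  const bool nn = (stdp_mode == 0 && nn_dep == 1);
  std::vector<double> pre_snap(nn ? n_syn : 0, 0.0);
  std::vector<double> lat_snap(nn ? (size_t)n_exc * n_exc : 0, 0.0);

  // spike delivery from previous step
  std::vector<int> prev_exc;
  bool prev_inh = false;

  // recording
  std::vector<int> out_neuron, out_bin;
  std::vector<double> vtrace;
  if (v_record_neuron >= 0) vtrace.reserve(n_steps);

  std::vector<int> snap_bins;
  std::vector<NumericMatrix> snap_lat, snap_ff;

  // scratch for input events of one neuron/step
  std::vector<int> ev;
  ev.reserve(64);
  std::vector<int> fired;
  fired.reserve(8);

  // schedule cursor
  int cur = 0;

  const double cr = dt / tau_r, cf = dt / tau_f, cm = dt / tau_m;

  for (int t = 0; t < n_steps; ++t) {
    // ---- presentation bookkeeping ----
    while (cur < n_sched && t >= sched_onset[cur] + pat_dur[sched_pat[cur]]) ++cur;
    bool in_pat = (cur < n_sched && t >= sched_onset[cur]);
    int pat_id = in_pat ? sched_pat[cur] : -1;
    int plo = 0, phi = 0;
    if (in_pat) {
      int rel = t - sched_onset[cur];
      plo = pstarts[pat_id][rel];
      phi = pstarts[pat_id][rel + 1];
    }

    // ---- decay post traces ----
    if (plastic) for (int j = 0; j < n_exc; ++j) post_trace[j] *= decay_d_step;

    // ---- lateral + inhibitory deliveries from previous step ----
    double I_inh_neuron = w_ei * (double)prev_exc.size();
    double I_inh_chan = prev_inh ? w_ie : 0.0;
    std::vector<double> I_lat(n_exc, 0.0);
    for (size_t ii = 0; ii < prev_exc.size(); ++ii) {
      int k = prev_exc[ii];
      if (lateral_scale > 0.0) {
        for (int j = 0; j < n_exc; ++j) {
          if (j == k) continue;
          I_lat[j] += lateral_scale * w_lat(k, j);
        }
      }
      if (plastic) {
        int lb = lat_last[k];
        for (int j = 0; j < n_exc; ++j) {
          if (j == k) continue;
          double dep = post_trace[j];
          if (nn) {
            size_t s = (size_t)k + (size_t)n_exc * j;
            if (lb >= 0) dep -= lat_snap[s] * Ed(t - lb);
            if (dep < 0.0) dep = 0.0;
            lat_snap[s] = post_trace[j];
          }
          double w = w_lat(k, j) + a_d_lat * dep;
          w_lat(k, j) = (w < 0.0) ? 0.0 : w;
        }
        lat_trace[k] = (lb < 0 ? 0.0 : lat_trace[k] * Ep(t - lb)) + 1.0;
        lat_last[k] = t;
      } else {
        lat_last[k] = t;  // still track for completeness (unused when frozen)
      }
    }

    // ---- afferent input generation + delivery ----
    std::vector<double> I_ff(n_exc, 0.0);
    for (int st = 0; st < n_streams; ++st) {
      Xoshiro &R = rng[st];
      ev.clear();
      // noise half: combined carrier+background all the time
      int k64 = bt_noise64.draw(R);
      for (int i = 0; i < k64; ++i) {
        int a;
        bool dup;
        do {
          a = n_pat_aff + (int)(R.unif() * n_noise_aff);
          if (a >= n_aff) a = n_aff - 1;
          dup = false;
          for (size_t q = 0; q < ev.size(); ++q) if (ev[q] == a) { dup = true; break; }
        } while (dup);
        ev.push_back(a);
      }
      // pattern half
      if (in_pat) {
        // background only (pattern spikes are added separately below)
        int k10 = bt_pat10.draw(R);
        for (int i = 0; i < k10; ++i) {
          int a;
          bool dup;
          do {
            a = (int)(R.unif() * n_pat_aff);
            if (a >= n_pat_aff) a = n_pat_aff - 1;
            dup = false;
            for (size_t q = 0; q < ev.size(); ++q) if (ev[q] == a) { dup = true; break; }
            if (!dup) {
              // collapse with a frozen-pattern spike in the same bin
              for (int q = plo; q < phi; ++q) if (pat_aff[q] == a) { dup = true; break; }
            }
          } while (dup);
          ev.push_back(a);
        }
      } else {
        int kp = bt_pat64.draw(R);
        for (int i = 0; i < kp; ++i) {
          int a;
          bool dup;
          do {
            a = (int)(R.unif() * n_pat_aff);
            if (a >= n_pat_aff) a = n_pat_aff - 1;
            dup = false;
            for (size_t q = 0; q < ev.size(); ++q) if (ev[q] == a) { dup = true; break; }
          } while (dup);
          ev.push_back(a);
        }
      }

      // deliver to neuron(s) fed by this stream
      int j0 = shared_noise ? 0 : st;
      int j1 = shared_noise ? n_exc : st + 1;
      for (int j = j0; j < j1; ++j) {
        double *wcol = &w_ff(0, j);
        double acc = 0.0;
        size_t base = (size_t)n_aff * j;
        for (size_t q = 0; q < ev.size(); ++q) {
          int a = ev[q];
          acc += wcol[a];
          if (plastic) {
            size_t s = base + a;
            int lb = pre_last[s];
            double dep = post_trace[j];
            if (nn) {
              if (lb >= 0) dep -= pre_snap[s] * Ed(t - lb);
              if (dep < 0.0) dep = 0.0;
              pre_snap[s] = post_trace[j];
            }
            double w = wcol[a] + a_d_ff * dep;
            wcol[a] = (w < 0.0) ? 0.0 : w;
            pre_trace[s] = (lb < 0 ? 0.0 : pre_trace[s] * Ep(t - lb)) + 1.0;
            pre_last[s] = t;
          }
        }
        I_ff[j] += acc;
      }
    }
    // frozen pattern spikes: shared across all neurons
    if (in_pat && phi > plo) {
      for (int j = 0; j < n_exc; ++j) {
        double *wcol = &w_ff(0, j);
        double acc = 0.0;
        size_t base = (size_t)n_aff * j;
        for (int q = plo; q < phi; ++q) {
          int a = pat_aff[q];
          acc += wcol[a];
          if (plastic) {
            size_t s = base + a;
            int lb = pre_last[s];
            double dep = post_trace[j];
            if (nn) {
              if (lb >= 0) dep -= pre_snap[s] * Ed(t - lb);
              if (dep < 0.0) dep = 0.0;
              pre_snap[s] = post_trace[j];
            }
            double w = wcol[a] + a_d_ff * dep;
            wcol[a] = (w < 0.0) ? 0.0 : w;
            pre_trace[s] = (lb < 0 ? 0.0 : pre_trace[s] * Ep(t - lb)) + 1.0;
            pre_last[s] = t;
          }
        }
        I_ff[j] += acc;
      }
    }

    // ---- forward Euler on filters and membranes (old values throughout) ----
    fired.clear();
    for (int j = 0; j < n_exc; ++j) {
      double sr_ff = Sr_ff[j], sf_ff = Sf_ff[j];
      double sr_lat = Sr_lat[j], sf_lat = Sf_lat[j];
      double sr_inh = Sr_inh[j], sf_inh = Sf_inh[j];
      double v = V[j];
      V[j] = v + cm * (-v + sf_ff + sf_lat - sf_inh);
      Sr_ff[j] = sr_ff + cr * (-sr_ff + I_ff[j]);
      Sf_ff[j] = sf_ff + cf * (-sf_ff + sr_ff);
      Sr_lat[j] = sr_lat + cr * (-sr_lat + I_lat[j]);
      Sf_lat[j] = sf_lat + cf * (-sf_lat + sr_lat);
      Sr_inh[j] = sr_inh + cr * (-sr_inh + I_inh_chan);
      Sf_inh[j] = sf_inh + cf * (-sf_inh + sr_inh);
      if (V[j] >= theta) fired.push_back(j);
    }
    {
      double v = Vi;
      Vi = v + cm * (-v + Sf_i);
      double sr = Sr_i, sf = Sf_i;
      Sr_i = sr + cr * (-sr + I_inh_neuron);
      Sf_i = sf + cf * (-sf + sr);
    }
    bool inh_fired = (Vi >= theta_inh);
    if (inh_fired) { Vi = 0.0; out_neuron.push_back(n_exc); out_bin.push_back(t); }

    if (v_record_neuron >= 0) vtrace.push_back(V[v_record_neuron]);

    // ---- threshold / reset / potentiation ----
    for (size_t fi = 0; fi < fired.size(); ++fi) {
      int j = fired[fi];
      V[j] = 0.0;
      out_neuron.push_back(j);
      out_bin.push_back(t);
      if (plastic) {
        // feed-forward potentiation
        double *wcol = &w_ff(0, j);
        size_t base = (size_t)n_aff * j;
        if (stdp_mode == 0) {
          for (int a = 0; a < n_aff; ++a) {
            int lb = pre_last[base + a];
            if (lb < 0) continue;
            double w = wcol[a] + a_p_ff * Ep(t - lb);
            wcol[a] = (w > wp_max) ? wp_max : w;
          }
        } else {
          for (int a = 0; a < n_aff; ++a) {
            size_t s = base + a;
            int lb = pre_last[s];
            if (lb < 0) continue;
            double w = wcol[a] + a_p_ff * pre_trace[s] * Ep(t - lb);
            wcol[a] = (w > wp_max) ? wp_max : w;
          }
        }
        // lateral potentiation (incoming synapses k -> j) + normalization
        double sum = 0.0;
        for (int k = 0; k < n_exc; ++k) {
          if (k == j) continue;
          int lb = lat_last[k];
          if (lb >= 0) {
            double val = (stdp_mode == 0) ? Ep(t - lb) : lat_trace[k] * Ep(t - lb);
            double w = w_lat(k, j) + a_p_lat * val;
            w_lat(k, j) = (w > wl_max) ? wl_max : w;
          }
          sum += w_lat(k, j);
        }
        if (sum > wl_max) {
          double sc = wl_max / sum;
          for (int k = 0; k < n_exc; ++k) if (k != j) w_lat(k, j) *= sc;
        }
        post_trace[j] += 1.0;
      }
    }

    prev_exc.assign(fired.begin(), fired.end());
    prev_inh = inh_fired;

    // ---- snapshots / sanity ----
    if (snapshot_every > 0 && ((t + 1) % snapshot_every == 0)) {
      snap_bins.push_back(t + 1);
      snap_lat.push_back(clone(w_lat));
      if (snapshot_ff) snap_ff.push_back(clone(w_ff));
    }
    if ((t & 1023) == 0) {
      for (int j = 0; j < n_exc; ++j)
        if (!std::isfinite(V[j])) stop("membrane potential diverged (non-finite V)");
      Rcpp::checkUserInterrupt();
    }
  }

  List snaps = List::create(
    _["bins"] = IntegerVector(snap_bins.begin(), snap_bins.end()),
    _["w_lat"] = wrap(snap_lat),
    _["w_ff"] = wrap(snap_ff));

  List out = List::create(
    _["spike_neuron"] = IntegerVector(out_neuron.begin(), out_neuron.end()),
    _["spike_bin"] = IntegerVector(out_bin.begin(), out_bin.end()),
    _["w_ff"] = w_ff,
    _["w_lat"] = w_lat,
    _["snapshots"] = snaps);
  if (v_record_neuron >= 0) out["v_trace"] = NumericVector(vtrace.begin(), vtrace.end());
  return out;
}

// ---------------------------------------------------------------------------
// Fast Bernoulli-per-bin spike train rendering for the stimulus module.
// Returns spike bins for a block of afferents over [0, n_bins) at per-bin
// probability p, as (afferent, bin) pairs. Used by render_stimulus().
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".bernoulli_raster_cpp")]]
List bernoulli_raster_cpp(int n_aff, int n_bins, double p, int seed, int stream) {
  std::vector<int> aff, bin;
  Xoshiro R;
  R.seed((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL +
         0xD1B54A32D192ED03ULL * (uint64_t)(uint32_t)(stream + 1));
  if (p > 0.0 && n_bins > 0) {
    // geometric skipping: number of failures before next success
    const double log1mp = std::log1p(-p);
    for (int a = 0; a < n_aff; ++a) {
      double u;
      long long b = -1;
      for (;;) {
        u = R.unif();
        double skip = std::floor(std::log1p(-u) / log1mp);
        b += 1 + (long long)skip;
        if (b >= n_bins) break;
        aff.push_back(a);
        bin.push_back((int)b);
      }
    }
  }
  return List::create(_["aff"] = IntegerVector(aff.begin(), aff.end()),
                      _["bin"] = IntegerVector(bin.begin(), bin.end()));
}
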