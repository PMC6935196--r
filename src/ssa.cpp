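// Exact stochastic simulation (Gillespie direct method) of the 6-channel
// birth-death system, plus helpers for the reduced one-variable chain:
// time-weighted occupancy and first-passage sampling.
//
// Randomness comes from a self-contained xoshiro256++ generator seeded via
// splitmix64, so trajectories are bit-reproducible for a given seed
// independently of R's RNG state and of the platform's standard library.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never 0, so -log(u) is finite
  inline double unif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  inline double exp_rv() { return -std::log(unif()); }
};

inline double hill_rep(double y, double K, double n) {
  double r = std::pow(y / K, n);
  if (!std::isfinite(r)) return 0.0;
  return 1.0 / (1.0 + r);
}

struct Params {
  double k1, k2, k3, k4, k5, k6, k7, k8, k9, k10;
  double K1, K2, K3, K4, K5, K6, n;
};

inline void channel_rates(const Params& p, double S, const double y[3],
                          double a[6]) {
  a[0] = p.k1 * S;                 // y1 birth
  a[1] = p.k2 * y[0];              // y1 death
  a[2] = p.k3 * (y[0] / (y[0] + p.K1)) +
         p.k4 * hill_rep(y[2], p.K2, p.n) +
         p.k9 * (p.K5 / (y[1] + p.K5));   // y2 birth
  a[3] = p.k5 * y[1];              // y2 death
  a[4] = p.k6 * (p.K3 / (y[0] + y[1] + p.K3)) +
         p.k7 * hill_rep(y[1], p.K4, p.n) +
         p.k10 * (p.K6 / (y[2] + p.K6));  // y3 birth
  a[5] = p.k8 * y[2];              // y3 death
}

Params unpack(const Rcpp::NumericVector& k, const Rcpp::NumericVector& K,
              double n) {
  Params p;
  p.k1 = k[0]; p.k2 = k[1]; p.k3 = k[2]; p.k4 = k[3]; p.k5 = k[4];
  p.k6 = k[5]; p.k7 = k[6]; p.k8 = k[7]; p.k9 = k[8]; p.k10 = k[9];
  p.K1 = K[0]; p.K2 = K[1]; p.K3 = K[2]; p.K4 = K[3]; p.K5 = K[4];
  p.K6 = K[5]; p.n = n;
  return p;
}

} // namespace

// Simulate one exact trajectory over [0, t_end] with the signal S equal to
// `amplitude` on [t_on, t_off) and 0 elsewhere, recording the state at the
// latest event <= t for each requested time. The waiting time is
// regenerated at the two switching instants (the propensities are constant
// between them).
// [[Rcpp::export]]
Rcpp::NumericMatrix ssa_trajectory_cpp(Rcpp::NumericVector k,
                                       Rcpp::NumericVector K, double n,
                                       double amplitude, double t_on,
                                       double t_off,
                                       Rcpp::NumericVector record_times,
                                       Rcpp::IntegerVector init,
                                       double seed) {
  Params p = unpack(k, K, n);
  Xoshiro rng(static_cast<uint64_t>(seed));
  const int nrec = record_times.size();
  Rcpp::NumericMatrix out(nrec, 3);

  double y[3] = {static_cast<double>(init[0]), static_cast<double>(init[1]),
                 static_cast<double>(init[2])};
  double t = 0.0;
  int irec = 0;
  double t_end = record_times[nrec - 1];

  // segment boundaries where S switches
  double bounds[3] = {t_on, t_off, t_end};
  double svals[3] = {0.0, amplitude, 0.0};
  // handle schedules with t_on == 0 etc. gracefully: segments of zero
  // length are skipped by the loop structure below.
  double a[6];
  for (int seg = 0; seg < 3; ++seg) {
    double seg_end = bounds[seg] < t_end ? bounds[seg] : t_end;
    double S = svals[seg];
    while (t < seg_end) {
      channel_rates(p, S, y, a);
      double a0 = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
      if (!(a0 > 0.0)) { t = seg_end; break; }
      if (!std::isfinite(a0))
        Rcpp::stop("non-finite propensity at state (%g, %g, %g)",
                   y[0], y[1], y[2]);
      double tau = rng.exp_rv() / a0;
      if (t + tau >= seg_end) { t = seg_end; break; }
      t += tau;
      // record states up to the event time
      while (irec < nrec && record_times[irec] < t) {
        out(irec, 0) = y[0]; out(irec, 1) = y[1]; out(irec, 2) = y[2];
        ++irec;
      }
      double r = rng.unif() * a0;
      int ch = 0;
      double acc = a[0];
      while (r > acc && ch < 5) acc += a[++ch];
      switch (ch) {
        case 0: y[0] += 1; break;
        case 1: y[0] -= 1; break;
        case 2: y[1] += 1; break;
        case 3: y[1] -= 1; break;
        case 4: y[2] += 1; break;
        case 5: y[2] -= 1; break;
      }
    }
    // flush records that fall inside the quiet tail of the segment
    while (irec < nrec && record_times[irec] <= t) {
      out(irec, 0) = y[0]; out(irec, 1) = y[1]; out(irec, 2) = y[2];
      ++irec;
    }
  }
  while (irec < nrec) {
    out(irec, 0) = y[0]; out(irec, 1) = y[1]; out(irec, 2) = y[2];
    ++irec;
  }
  return out;
}

// Time-weighted occupancy of the reduced birth-death chain after `n_events`
// events, starting from `init`. `birth` is the tabulated birth rate for
// states 0..length(birth)-1 (birth at the top state is treated as 0, i.e.
// reflecting); the death rate is kdeath * state.
// [[Rcpp::export]]
Rcpp::NumericVector chain_occupancy_cpp(Rcpp::NumericVector birth,
                                        double kdeath, int init,
                                        double n_events, double seed,
                                        double burnin_events) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  const int cap = birth.size() - 1;
  std::vector<double> occ(cap + 1, 0.0);
  int y = init;
  double done = 0.0;
  while (done < n_events + burnin_events) {
    double wb = (y < cap) ? birth[y] : 0.0;
    double wd = kdeath * y;
    double a0 = wb + wd;
    if (!(a0 > 0.0)) Rcpp::stop("absorbing state reached at y = %d", y);
    double tau = rng.exp_rv() / a0;
    if (done >= burnin_events) occ[y] += tau;
    double r = rng.unif() * a0;
    y += (r < wb) ? 1 : -1;
    done += 1.0;
  }
  double tot = 0.0;
  for (double v : occ) tot += v;
  Rcpp::NumericVector out(cap + 1);
  for (int i = 0; i <= cap; ++i) out[i] = occ[i] / tot;
  return out;
}

// First-passage times of the reduced chain from `start` to `absorb`
// (either direction), n_reps independent replicates.
// [[Rcpp::export]]
Rcpp::NumericVector chain_first_passage_cpp(Rcpp::NumericVector birth,
                                            double kdeath, int start,
                                            int absorb, int n_reps,
                                            double seed,
                                            double max_events) {
  const int cap = birth.size() - 1;
  Rcpp::NumericVector out(n_reps);
  for (int r = 0; r < n_reps; ++r) {
    Xoshiro rng(static_cast<uint64_t>(seed) + static_cast<uint64_t>(r));
    int y = start;
    double t = 0.0;
    double ev = 0.0;
    while (y != absorb) {
      double wb = (y < cap) ? birth[y] : 0.0;
      double wd = kdeath * y;
      double a0 = wb + wd;
      if (!(a0 > 0.0)) Rcpp::stop("absorbing state reached at y = %d", y);
      t += rng.exp_rv() / a0;
      double u = rng.unif() * a0;
      y += (u < wb) ? 1 : -1;
      if (++ev > max_events)
        Rcpp::stop("first passage not reached within %g events", max_events);
    }
    out[r] = t;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
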