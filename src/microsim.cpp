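// Annual-cycle individual-level state-transition engine.
//
// Randomness is counter-based: every decision draws a uniform keyed by
// (master seed, person, age, channel), so identical seeds give identical
// draws per decision channel across counterfactual scenarios (common random
// numbers) without storing streams. Channels: 0 death, 1 incidence/relapse,
// 2 ED-type pick, 3 treatment assignment, 4 remission/crossover outcome.
//
// Channels 0 and 1 are consulted for almost every person-year; callers
// running many evaluations under a fixed seed (simulated annealing) can
// pregenerate them once with ed_streams_cpp() and pass them back in.
//
// The life course of most persons is an unbroken healthy run, so the
// person loop has a tight "never-affected" scan (death + onset checks
// only) and drops into the full state machine at first onset. Healthy
// occupancy is recovered at the end by difference (alive minus ED states),
// and deceased occupancy by cumulating deaths, so the scan touches no
// per-state accumulators.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static const int HEALTHY = 1, DECEASED = 6;
static const int NAGE = 40;

static inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double u01(uint64_t seed, uint32_t person, uint32_t age,
                         uint32_t channel) {
  uint64_t key = mix64(seed + 0x9E3779B97F4A7C15ULL * (uint64_t)(person + 1));
  key = mix64(key + 0xC2B2AE3D27D4EB4FULL * (uint64_t)(age * 8 + channel + 1));
  return (double)(key >> 11) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export]]
List ed_streams_cpp(int n, double seed) {
  uint64_t s = (uint64_t)seed;
  NumericMatrix u0(NAGE, n), u1(NAGE, n);
  for (int p = 0; p < n; ++p)
    for (int a = 0; a < NAGE; ++a) {
      u0(a, p) = u01(s, p, a, 0);
      u1(a, p) = u01(s, p, a, 1);
    }
  return List::create(_["u0"] = u0, _["u1"] = u1);
}

// [[Rcpp::export]]
List sim_cohort_cpp(NumericVector inc,        // [4 ed, 2 sex, 40 age]
                    NumericMatrix relapse_first,  // [4, 2]
                    NumericMatrix relapse_decay,  // [4, 2]
                    NumericMatrix remission,      // [4, 2]
                    NumericMatrix treat_coverage, // [4, 2]
                    NumericMatrix treat_rr,       // [4, 2]
                    NumericVector crossover,      // [4 from, 4 to, 2 sex]
                    NumericMatrix smr,            // [4, 2]
                    NumericMatrix q_bg,           // [2 sex, 40 age]
                    int treatment_mode,           // 0 current, 1 none, 2 full
                    bool incidence_on,
                    int n, double seed, bool record_full,
                    Nullable<NumericMatrix> stream0 = R_NilValue,
                    Nullable<NumericMatrix> stream1 = R_NilValue) {
  const uint64_t S = (uint64_t)seed;
  const int n_male = n / 2;

  // --- precomputed tables ---
  double qrow[2][NAGE];
  double tot_inc[2][NAGE];
  double cum_frac[2][NAGE][4];
  double p_die_ed[4][2][NAGE];
  double prem_base[4][2], prem_treat[4][2];
  double relapse_tab[4][2][NAGE + 1];  // by years since remission (1..40)
  double cross_cum[4][2][4];
  int    cross_dest[4][4];
  for (int s = 0; s < 2; ++s)
    for (int a = 0; a < NAGE; ++a) {
      qrow[s][a] = q_bg(s, a);
      double t = 0.0;
      for (int e = 0; e < 4; ++e) {
        double v = incidence_on ? inc[e + 4 * s + 8 * a] : 0.0;
        t += v;
        cum_frac[s][a][e] = t;
      }
      tot_inc[s][a] = t;
      if (t > 0) for (int e = 0; e < 4; ++e) cum_frac[s][a][e] /= t;
    }
  for (int e = 0; e < 4; ++e)
    for (int s = 0; s < 2; ++s) {
      prem_base[e][s] = remission(e, s);
      prem_treat[e][s] = 1.0 - std::pow(1.0 - remission(e, s), treat_rr(e, s));
      for (int a = 0; a < NAGE; ++a)
        p_die_ed[e][s][a] = 1.0 - std::pow(1.0 - qrow[s][a], smr(e, s));
      for (int y = 1; y <= NAGE; ++y)
        relapse_tab[e][s][y] = relapse_first(e, s) *
          std::exp(-relapse_decay(e, s) * (double)(y - 1));
      int k = 0;
      for (int j = 0; j < 4; ++j) {
        if (j == e) continue;
        double prev = (k == 0) ? 0.0 : cross_cum[e][s][k - 1];
        cross_cum[e][s][k] = prev + crossover[e + 4 * j + 16 * s];
        cross_dest[e][k] = j;
        ++k;
      }
    }

  const double *U0 = nullptr, *U1 = nullptr;
  NumericMatrix m0, m1;
  if (stream0.isNotNull()) { m0 = NumericMatrix(stream0.get()); U0 = m0.begin(); }
  if (stream1.isNotNull()) { m1 = NumericMatrix(stream1.get()); U1 = m1.begin(); }

  // --- accumulators ---
  int ed_occ[4][2][NAGE + 1];      // occupancy of each ED state
  int deaths_new[2][NAGE + 1];     // newly deceased at each age column
  std::fill(&ed_occ[0][0][0], &ed_occ[0][0][0] + 4 * 2 * (NAGE + 1), 0);
  std::fill(&deaths_new[0][0], &deaths_new[0][0] + 2 * (NAGE + 1), 0);
  IntegerVector onset_counts(2 * (NAGE + 1));
  IntegerVector first_ed_counts(4 * 2 * (NAGE + 1));
  IntegerVector epi_any(6 * 2);
  IntegerVector epi_ed(4 * 6 * 2);

  IntegerMatrix states_full(record_full ? n : 0, record_full ? NAGE + 1 : 0);
  IntegerMatrix treated_full(record_full ? n : 0, record_full ? NAGE : 0);
  IntegerVector onset_age_full(record_full ? n : 0);
  if (record_full) std::fill(states_full.begin(), states_full.end(), HEALTHY);

  for (int p = 0; p < n; ++p) {
    const int s = (p < n_male) ? 0 : 1;
    const double *u0p = U0 ? U0 + (size_t)NAGE * p : nullptr;
    const double *u1p = U1 ? U1 + (size_t)NAGE * p : nullptr;
    int state = HEALTHY;
    int last_ed = -1, ysr = 0, onset_age = -1;
    bool ever_ed_p[4] = {false, false, false, false};
    int n_epi_any = 0, n_epi_ed[4] = {0, 0, 0, 0};
    int a = 0;

    // fast never-affected scan: healthy, no history
    for (; a < NAGE; ++a) {
      const double u0 = u0p ? u0p[a] : u01(S, p, a, 0);
      if (u0 < qrow[s][a]) { state = DECEASED; ++a; break; }
      const double ti = tot_inc[s][a];
      if (ti > 0.0) {
        const double u1 = u1p ? u1p[a] : u01(S, p, a, 1);
        if (u1 < ti) {
          const double u2 = u01(S, p, a, 2);
          int e = 3;
          for (int j = 0; j < 4; ++j)
            if (u2 < cum_frac[s][a][j]) { e = j; break; }
          state = e + 2;
          ever_ed_p[e] = true;
          last_ed = e;
          onset_age = a + 1;
          ++onset_counts[s + 2 * (a + 1)];
          ++first_ed_counts[e + 4 * s + 8 * (a + 1)];
          ++n_epi_any;
          ++n_epi_ed[e];
          ++a;
          break;
        }
      }
    }

    if (state == DECEASED) {
      ++deaths_new[s][a];
      if (record_full)
        for (int b = a; b <= NAGE; ++b) states_full(p, b) = DECEASED;
    } else if (state != HEALTHY) {
      // affected: full state machine from first onset
      for (; a <= NAGE; ++a) {
        if (state >= 2 && state <= 5) ++ed_occ[state - 2][s][a];
        if (record_full) states_full(p, a) = state;
        if (a == NAGE) break;
        if (state == HEALTHY) {
          const double u0 = u0p ? u0p[a] : u01(S, p, a, 0);
          if (u0 < qrow[s][a]) {
            ++deaths_new[s][a + 1];
            if (record_full)
              for (int b = a + 1; b <= NAGE; ++b) states_full(p, b) = DECEASED;
            break;
          }
          const double pr = relapse_tab[last_ed][s][ysr > NAGE ? NAGE : ysr];
          const double u1 = u1p ? u1p[a] : u01(S, p, a, 1);
          if (u1 < pr) {
            state = last_ed + 2;
            ++n_epi_any;
            ++n_epi_ed[last_ed];
          } else ++ysr;
        } else {
          const int e = state - 2;
          const double u0 = u0p ? u0p[a] : u01(S, p, a, 0);
          if (u0 < p_die_ed[e][s][a]) {
            ++deaths_new[s][a + 1];
            if (record_full)
              for (int b = a + 1; b <= NAGE; ++b) states_full(p, b) = DECEASED;
            break;
          }
          bool treated = false;
          if (treatment_mode == 2) treated = true;
          else if (treatment_mode == 0)
            treated = u01(S, p, a, 3) < treat_coverage(e, s);
          if (record_full && treated) treated_full(p, a) = 1;
          const double prem = treated ? prem_treat[e][s] : prem_base[e][s];
          const double u4 = u01(S, p, a, 4);
          if (u4 < prem) {
            state = HEALTHY;
            last_ed = e;
            ysr = 1;
          } else {
            for (int k = 0; k < 3; ++k) {
              if (u4 < prem + cross_cum[e][s][k]) {
                const int j = cross_dest[e][k];
                state = j + 2;
                last_ed = j;
                if (!ever_ed_p[j]) {
                  ever_ed_p[j] = true;
                  ++first_ed_counts[j + 4 * s + 8 * (a + 1)];
                }
                ++n_epi_ed[j];
                break;
              }
            }
          }
        }
      }
    }

    const int bin = n_epi_any > 5 ? 5 : n_epi_any;
    ++epi_any[bin + 6 * s];
    for (int e = 0; e < 4; ++e) {
      const int be = n_epi_ed[e] > 5 ? 5 : n_epi_ed[e];
      ++epi_ed[e + 4 * be + 24 * s];
    }
    if (record_full) onset_age_full[p] = onset_age;
  }

  // assemble state occupancy: deceased by cumulating deaths, healthy by
  // difference
  IntegerVector state_counts(6 * 2 * (NAGE + 1));
  for (int s = 0; s < 2; ++s) {
    const int ns = (s == 0) ? n_male : n - n_male;
    int dead = 0;
    for (int a = 0; a <= NAGE; ++a) {
      dead += deaths_new[s][a];
      int edsum = 0;
      for (int e = 0; e < 4; ++e) {
        state_counts[(e + 1) + 6 * s + 12 * a] = ed_occ[e][s][a];
        edsum += ed_occ[e][s][a];
      }
      state_counts[(DECEASED - 1) + 6 * s + 12 * a] = dead;
      state_counts[0 + 6 * s + 12 * a] = ns - dead - edsum;
    }
  }

  state_counts.attr("dim") = IntegerVector::create(6, 2, NAGE + 1);
  onset_counts.attr("dim") = IntegerVector::create(2, NAGE + 1);
  first_ed_counts.attr("dim") = IntegerVector::create(4, 2, NAGE + 1);
  epi_any.attr("dim") = IntegerVector::create(6, 2);
  epi_ed.attr("dim") = IntegerVector::create(4, 6, 2);

  List out = List::create(
    _["state_counts"] = state_counts,
    _["onset_counts"] = onset_counts,
    _["first_ed_counts"] = first_ed_counts,
    _["episodes_any"] = epi_any,
    _["episodes_ed"] = epi_ed);
  if (record_full) {
    out["states"] = states_full;
    out["treated"] = treated_full;
    out["onset_age"] = onset_age_full;
  }
  return out;
}
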