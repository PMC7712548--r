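// Stochastic kernels: overdamped 1D Brownian walker on a gridded
// free-energy profile (Euler-Maruyama) and the exact event-driven
// simulator of the three-site occupancy chain.  Both draw from R's RNG so
// set.seed() governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

// linear interpolation of the (negative) free-energy gradient, clamped to
// the end values outside the grid
static inline double interp_grad(const double z,
                                 const NumericVector& zg,
                                 const NumericVector& g) {
  const int n = zg.size();
  if (z <= zg[0]) return g[0];
  if (z >= zg[n - 1]) return g[n - 1];
  // grid is uniform in practice but do a binary search to be safe
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    const int mid = (lo + hi) / 2;
    if (zg[mid] <= z) lo = mid; else hi = mid;
  }
  const double w = (z - zg[lo]) / (zg[hi] - zg[lo]);
  return g[lo] + w * (g[hi] - g[lo]);
}

// [[Rcpp::export]]
List cpp_walk(NumericVector zgrid, NumericVector dFdz, double D, double dt,
              int n_walkers, double z0, double z_minus, double z_plus,
              bool reflect_lower, double t_max, double max_steps,
              int n_store, int store_stride) {
  IntegerVector outcome(n_walkers);   // 0 reflected, 1 translocated, 2 active
  NumericVector exit_time(n_walkers);
  NumericVector max_z(n_walkers);
  NumericVector final_z(n_walkers);
  List traj(std::max(0, std::min(n_store, n_walkers)));
  const double noise = std::sqrt(2.0 * D * dt);
  bool hit_cap = false;

  for (int w = 0; w < n_walkers; ++w) {
    double z = z0, mz = z0;
    long long steps = 0;
    int out = 2;
    std::vector<double> path;
    const bool store = (w < n_store);
    if (store) path.push_back(z);
    while (true) {
      if (t_max > 0 && steps * dt >= t_max) { out = 2; break; }
      if ((double)steps >= max_steps) { out = 2; hit_cap = true; break; }
      const double drift = -D * interp_grad(z, zgrid, dFdz); // F in kBT
      z += drift * dt + noise * norm_rand();
      ++steps;
      if (z > mz) mz = z;
      if (store && steps % store_stride == 0)
        path.push_back(z);
      if (z >= z_plus) { out = 1; z = z_plus; break; }
      if (z <= z_minus) {
        if (reflect_lower) {
          z = 2.0 * z_minus - z;
          if (z >= z_plus) { out = 1; z = z_plus; break; } // pathological dt
        } else { out = 0; z = z_minus; break; }
      }
    }
    outcome[w] = out;
    exit_time[w] = steps * dt;
    max_z[w] = mz;
    final_z[w] = z;
    if (store) { path.push_back(z); traj[w] = wrap(path); }
    if (w % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["outcome"] = outcome, _["exit_time"] = exit_time,
                      _["max_z"] = max_z, _["final_z"] = final_z,
                      _["trajectories"] = traj, _["hit_step_cap"] = hit_cap);
}

// Event-driven simulation of the three-site chain.  Site occupancies are
// binary; transitions (one-way through the pore site, optional backward
// rates):
//   1: bulk -> site1        kb (1-s1)
//   2: site1 -> bulk        kb_out s1
//   3: site1 -> site2       ka s1 (1-s2)
//   4: site2 -> site3       kd s2 (1-s3)      [counted as translocation]
//   5: site3 -> bulk        kexit_out s3
//   6: bulk -> site3        kexit_in (1-s3)
//   7: site2 -> site1       ka_back s2 (1-s1)
//   8: site3 -> site2       kd_back s3 (1-s2)
// [[Rcpp::export]]
List cpp_gillespie(double kb, double kb_out, double ka, double kd,
                   double kexit_in, double kexit_out,
                   double ka_back, double kd_back,
                   double t_end, double t_burn, bool record, int max_events) {
  int s1 = 0, s2 = 0, s3 = 0;
  double t = 0.0;
  double occ1 = 0.0, occ2 = 0.0, occ3 = 0.0;
  std::vector<double> ev_time;
  std::vector<int> ev_type;
  IntegerVector counts(8);
  double rates[8];
  long n_events = 0;

  while (t < t_end) {
    rates[0] = kb * (1 - s1);
    rates[1] = kb_out * s1;
    rates[2] = ka * s1 * (1 - s2);
    rates[3] = kd * s2 * (1 - s3);
    rates[4] = kexit_out * s3;
    rates[5] = kexit_in * (1 - s3);
    rates[6] = ka_back * s2 * (1 - s1);
    rates[7] = kd_back * s3 * (1 - s2);
    double total = 0.0;
    for (int i = 0; i < 8; ++i) total += rates[i];
    if (total <= 0.0) break;  // absorbing state; occupancies persist to t_end
    const double dt = -std::log(unif_rand()) / total;
    const double t_next = t + dt;
    const double span =
      std::max(0.0, std::min(t_next, t_end) - std::max(t, t_burn));
    occ1 += span * s1; occ2 += span * s2; occ3 += span * s3;
    if (t_next >= t_end) { t = t_end; break; }
    t = t_next;
    double u = unif_rand() * total;
    int e = 0;
    for (; e < 7; ++e) { if (u < rates[e]) break; u -= rates[e]; }
    switch (e) {
      case 0: s1 = 1; break;
      case 1: s1 = 0; break;
      case 2: s1 = 0; s2 = 1; break;
      case 3: s2 = 0; s3 = 1; break;
      case 4: s3 = 0; break;
      case 5: s3 = 1; break;
      case 6: s2 = 0; s1 = 1; break;
      case 7: s3 = 0; s2 = 1; break;
    }
    if (t >= t_burn) counts[e] += 1;
    if (record && (int)ev_time.size() < max_events) {
      ev_time.push_back(t);
      ev_type.push_back(e + 1);
    }
    if ((++n_events & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  // tail interval when the chain went absorbing before t_end
  if (t < t_end) {
    const double span = std::max(0.0, t_end - std::max(t, t_burn));
    occ1 += span * s1; occ2 += span * s2; occ3 += span * s3;
  }
  const double t_obs = t_end - t_burn;
  return List::create(_["P1"] = occ1 / t_obs, _["P2"] = occ2 / t_obs,
                      _["P3"] = occ3 / t_obs,
                      _["counts"] = counts,
                      _["translocations"] = counts[3],
                      _["event_time"] = wrap(ev_time),
                      _["event_type"] = wrap(ev_type));
}
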