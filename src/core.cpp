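#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// BAOAB Langevin integrator over a bead-spring system with a frozen subset.
// Potential: harmonic bonds, WCA (purely repulsive) excluded volume between
// every mobile-any non-bonded pair, and optional Gaussian attraction wells
// between each mobile bead and designated site beads.
// Uses R's RNG (norm_rand) so set.seed() in R gives bit determinism.

static inline long long pair_key(int i, int j, int n) {
  return (long long)std::min(i, j) * n + std::max(i, j);
}

struct ForceField {
  int n;
  const std::vector<int> &mob;      // mobile bead indices
  const std::vector<char> &is_mob;
  const IntegerMatrix &bonds;       // 0-based pairs
  double k_bond, r0;
  double sigma2, wca_cut2;          // cutoff^2 = 2^(1/3) sigma^2
  const NumericMatrix &wells;       // cols: site index (0-based), eps, rw
  std::unordered_set<long long> bonded;

  ForceField(int n_, const std::vector<int> &mob_, const std::vector<char> &ismob_,
             const IntegerMatrix &bonds_, double kb, double r0_, double sigma,
             const NumericMatrix &wells_)
    : n(n_), mob(mob_), is_mob(ismob_), bonds(bonds_), k_bond(kb), r0(r0_),
      sigma2(sigma * sigma), wca_cut2(std::pow(2.0, 1.0 / 3.0) * sigma * sigma),
      wells(wells_) {
    for (int b = 0; b < bonds.nrow(); ++b)
      bonded.insert(pair_key(bonds(b, 0), bonds(b, 1), n));
  }

  void compute(const std::vector<double> &x, std::vector<double> &F) const {
    std::fill(F.begin(), F.end(), 0.0);
    // harmonic bonds
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0), j = bonds(b, 1);
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double fmag = -k_bond * (r - r0) / r;  // force on i along (i - j)
      F[3 * i] += fmag * dx;     F[3 * i + 1] += fmag * dy;     F[3 * i + 2] += fmag * dz;
      F[3 * j] -= fmag * dx;     F[3 * j + 1] -= fmag * dy;     F[3 * j + 2] -= fmag * dz;
    }
    // WCA excluded volume: each mobile-any pair once, bonded pairs excluded
    for (size_t a = 0; a < mob.size(); ++a) {
      int i = mob[a];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (is_mob[j] && j < i) continue;  // mobile-mobile counted once
        if (bonded.count(pair_key(i, j, n))) continue;
        double dx = x[3 * i] - x[3 * j];
        double dy = x[3 * i + 1] - x[3 * j + 1];
        double dz = x[3 * i + 2] - x[3 * j + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= wca_cut2 || r2 < 1e-12) continue;
        double s2 = sigma2 / r2;
        double s6 = s2 * s2 * s2;
        // U = 4[(s/r)^12 - (s/r)^6] + 1 (eps_wca = kT unit); F = 24(2 s12 - s6)/r^2 * rvec
        double fmag = 24.0 * (2.0 * s6 * s6 - s6) / r2;
        F[3 * i] += fmag * dx;     F[3 * i + 1] += fmag * dy;     F[3 * i + 2] += fmag * dz;
        if (is_mob[j]) {
          F[3 * j] -= fmag * dx;   F[3 * j + 1] -= fmag * dy;   F[3 * j + 2] -= fmag * dz;
        }
      }
    }
    // Gaussian attraction wells: U = -eps * exp(-r^2 / (2 rw^2)), truncated at 3.5 rw
    for (int w = 0; w < wells.nrow(); ++w) {
      int s = (int)wells(w, 0);
      double eps = wells(w, 1), rw = wells(w, 2);
      double trunc2 = 12.25 * rw * rw;
      for (size_t a = 0; a < mob.size(); ++a) {
        int i = mob[a];
        if (i == s) continue;
        double dx = x[3 * i] - x[3 * s];
        double dy = x[3 * i + 1] - x[3 * s + 1];
        double dz = x[3 * i + 2] - x[3 * s + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= trunc2) continue;
        double g = -eps * std::exp(-r2 / (2.0 * rw * rw)) / (rw * rw);  // F = g * rvec
        F[3 * i] += g * dx;  F[3 * i + 1] += g * dy;  F[3 * i + 2] += g * dz;
        if (is_mob[s]) {
          F[3 * s] -= g * dx;  F[3 * s + 1] -= g * dy;  F[3 * s + 2] -= g * dz;
        }
      }
    }
  }
};

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords0, LogicalVector mobile,
                      IntegerMatrix bonds, double k_bond, double r0,
                      double sigma, NumericMatrix wells, double kT,
                      double gamma, double dt, double mass, int n_steps,
                      IntegerVector record_steps) {
  const int n = coords0.nrow();
  std::vector<int> mob;
  std::vector<char> is_mob(n, 0);
  for (int i = 0; i < n; ++i)
    if (mobile[i]) { mob.push_back(i); is_mob[i] = 1; }
  const int n_mob = (int)mob.size();

  std::vector<double> x(3 * n), v(3 * n, 0.0), F(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords0(i, d);

  // Maxwell-Boltzmann start for mobile beads
  double vscale = std::sqrt(kT / mass);
  for (int a = 0; a < n_mob; ++a)
    for (int d = 0; d < 3; ++d) v[3 * mob[a] + d] = vscale * norm_rand();

  ForceField ff(n, mob, is_mob, bonds, k_bond, r0, sigma, wells);
  ff.compute(x, F);

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT / mass);
  const double hdtm = 0.5 * dt / mass;

  const int n_frames = record_steps.size();
  NumericVector frames(Dimension(n_frames, n, 3));
  NumericVector frame_temp(n_frames);
  int next_rec = 0;

  auto record = [&](int step) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double val = x[3 * i + d];
        if (!R_finite(val))
          stop("integration failure: non-finite coordinate at step %d", step);
        frames[next_rec + n_frames * (i + n * d)] = val;
      }
    double ke = 0.0;
    for (int a = 0; a < n_mob; ++a)
      for (int d = 0; d < 3; ++d) {
        double vv = v[3 * mob[a] + d];
        ke += mass * vv * vv;
      }
    frame_temp[next_rec] = n_mob > 0 ? ke / (3.0 * n_mob) : NA_REAL;
    ++next_rec;
  };

  if (next_rec < n_frames && record_steps[next_rec] == 0) record(0);

  double ke_sum = 0.0;
  long ke_count = 0;
  const int half = n_steps / 2;

  for (int step = 1; step <= n_steps; ++step) {
    for (int a = 0; a < n_mob; ++a) {
      int i = mob[a];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += hdtm * F[3 * i + d];
    }
    for (int a = 0; a < n_mob; ++a) {
      int i = mob[a];
      for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * v[3 * i + d];
    }
    for (int a = 0; a < n_mob; ++a) {
      int i = mob[a];
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] = c1 * v[3 * i + d] + c2 * norm_rand();
    }
    for (int a = 0; a < n_mob; ++a) {
      int i = mob[a];
      for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * v[3 * i + d];
    }
    ff.compute(x, F);
    for (int a = 0; a < n_mob; ++a) {
      int i = mob[a];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += hdtm * F[3 * i + d];
    }
    if (step > half && n_mob > 0) {
      for (int a = 0; a < n_mob; ++a)
        for (int d = 0; d < 3; ++d) {
          double vv = v[3 * mob[a] + d];
          ke_sum += mass * vv * vv;
        }
      ++ke_count;
    }
    if (next_rec < n_frames && record_steps[next_rec] == step) record(step);
  }

  double kin_T = (ke_count > 0 && n_mob > 0)
    ? ke_sum / (3.0 * n_mob * ke_count) : NA_REAL;

  return List::create(_["frames"] = frames,
                      _["frame_temperature"] = frame_temp,
                      _["kinetic_temperature"] = kin_T);
}

// Residue-residue contact accumulation over frames.
// frames: array (n_frames x n_atoms x 3); res_index: 0-based global residue
// index per atom; mode 0 = contact frequency (min distance < cutoff),
// mode 1 = mean smallest distance clamped at cutoff.
// [[Rcpp::export]]
NumericMatrix cpp_contact_map(NumericVector frames, IntegerVector res_index,
                              int n_res, int mode, double cutoff) {
  IntegerVector dims = frames.attr("dim");
  const int nF = dims[0], nA = dims[1];
  const double cut2 = cutoff * cutoff;
  const double BIG = 1e300;

  std::vector<double> mind2((size_t)n_res * n_res);
  std::vector<double> acc((size_t)n_res * n_res, 0.0);

  for (int f = 0; f < nF; ++f) {
    std::fill(mind2.begin(), mind2.end(), BIG);
    for (int i = 0; i < nA; ++i) {
      int gi = res_index[i];
      double xi = frames[f + nF * (i + nA * 0)];
      double yi = frames[f + nF * (i + nA * 1)];
      double zi = frames[f + nF * (i + nA * 2)];
      for (int j = i + 1; j < nA; ++j) {
        int gj = res_index[j];
        if (gi == gj) continue;
        double dx = xi - frames[f + nF * (j + nA * 0)];
        double dy = yi - frames[f + nF * (j + nA * 1)];
        double dz = zi - frames[f + nF * (j + nA * 2)];
        double d2 = dx * dx + dy * dy + dz * dz;
        size_t k = (size_t)std::min(gi, gj) * n_res + std::max(gi, gj);
        if (d2 < mind2[k]) mind2[k] = d2;
      }
    }
    for (int a = 0; a < n_res; ++a)
      for (int b = a + 1; b < n_res; ++b) {
        size_t k = (size_t)a * n_res + b;
        if (mind2[k] >= BIG) continue;  // residue pair absent from atom set
        if (mode == 0) {
          if (mind2[k] < cut2) acc[k] += 1.0;
        } else {
          double d = std::sqrt(mind2[k]);
          acc[k] += d < cutoff ? d : cutoff;
        }
      }
  }

  NumericMatrix M(n_res, n_res);
  for (int a = 0; a < n_res; ++a) {
    M(a, a) = (mode == 0) ? 1.0 : 0.0;
    for (int b = a + 1; b < n_res; ++b) {
      double val = acc[(size_t)a * n_res + b] / nF;
      M(a, b) = val;
      M(b, a) = val;
    }
  }
  return M;
}
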