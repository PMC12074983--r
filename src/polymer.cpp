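#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bead-spring chromatin polymer, Metropolis Monte Carlo at kT = 1.
// Energy: harmonic bonds 0.5*k*(r-l0)^2 between consecutive beads;
// nonbonded pairs (|i-j| >= 2): hard core below `hardcore`, square
// well of depth K between `hardcore` and `cutoff`. Moves: single-bead
// random displacement and crankshaft rotation about the neighbor axis.

static inline double dist2(const NumericMatrix &x, int i, int j) {
  double dx = x(i, 0) - x(j, 0);
  double dy = x(i, 1) - x(j, 1);
  double dz = x(i, 2) - x(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

static double bead_energy(const NumericMatrix &x, int i,
                          double px, double py, double pz,
                          double bond_k, double bond_l0, double K,
                          double cutoff2, double hardcore2,
                          bool excluded_volume, bool &overlap) {
  int n = x.nrow();
  double e = 0.0;
  overlap = false;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = px - x(j, 0), dy = py - x(j, 1), dz = pz - x(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    int sep = j > i ? j - i : i - j;
    if (sep == 1) {
      double r = std::sqrt(r2);
      e += 0.5 * bond_k * (r - bond_l0) * (r - bond_l0);
    } else {
      if (excluded_volume && r2 < hardcore2) { overlap = true; return 0.0; }
      if (r2 < cutoff2) e -= K;
    }
  }
  return e;
}

// [[Rcpp::export(name = ".polymer_total_energy")]]
double polymer_total_energy(NumericMatrix x, double bond_k,
                            double bond_l0, double K, double cutoff,
                            double hardcore, bool excluded_volume) {
  int n = x.nrow();
  double cutoff2 = cutoff * cutoff, hardcore2 = hardcore * hardcore;
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    double r = std::sqrt(dist2(x, i, i + 1));
    e += 0.5 * bond_k * (r - bond_l0) * (r - bond_l0);
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j) {
      double r2 = dist2(x, i, j);
      if (excluded_volume && r2 < hardcore2) return R_PosInf;
      if (r2 < cutoff2) e -= K;
    }
  return e;
}

// [[Rcpp::export(name = ".polymer_mc")]]
List polymer_mc(int n_beads, double bond_k, double bond_l0, double K,
                double cutoff, double hardcore, int n_sweeps,
                double max_disp, bool excluded_volume,
                bool recheck_energy) {
  NumericMatrix x(n_beads, 3);
  double cutoff2 = cutoff * cutoff, hardcore2 = hardcore * hardcore;

  // initial conformation: self-avoiding growth at the bond rest
  // length so the hard core is respected from the start
  for (int i = 1; i < n_beads; ++i) {
    int tries = 0;
    while (true) {
      double u = 2.0 * unif_rand() - 1.0;
      double phi = 2.0 * M_PI * unif_rand();
      double s = std::sqrt(1.0 - u * u);
      x(i, 0) = x(i - 1, 0) + bond_l0 * s * std::cos(phi);
      x(i, 1) = x(i - 1, 1) + bond_l0 * s * std::sin(phi);
      x(i, 2) = x(i - 1, 2) + bond_l0 * u;
      if (!excluded_volume) break;
      bool clash = false;
      for (int j = 0; j <= i - 2; ++j)
        if (dist2(x, i, j) < hardcore2 * 1.0001) { clash = true; break; }
      if (!clash || ++tries > 500) break;
    }
  }
  double energy = polymer_total_energy(x, bond_k, bond_l0, K, cutoff,
                                       hardcore, excluded_volume);

  long accepted = 0, attempted = 0;
  // linear ramp of the well depth over the first half of the run
  // (gradual quench; avoids kinetic trapping in necklace states)
  int n_anneal = n_sweeps / 2;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    double K_now = (sweep < n_anneal)
      ? K * (double)(sweep + 1) / (double)n_anneal : K;
    if (sweep == n_anneal || (n_anneal == 0 && sweep == 0)) {
      // well depth reached its target: rebase the running energy and
      // the acceptance diagnostics on the production phase
      energy = polymer_total_energy(x, bond_k, bond_l0, K, cutoff,
                                    hardcore, excluded_volume);
      accepted = 0; attempted = 0;
    }
    for (int m = 0; m < n_beads; ++m) {
      int i = (int)(unif_rand() * n_beads);
      if (i >= n_beads) i = n_beads - 1;
      double nx = 0.0, ny = 0.0, nz = 0.0;
      bool crank = (unif_rand() < 0.5) && i > 0 && i < n_beads - 1;
      if (crank) {
        // rotate bead i about the axis through its neighbors
        double ax = x(i + 1, 0) - x(i - 1, 0);
        double ay = x(i + 1, 1) - x(i - 1, 1);
        double az = x(i + 1, 2) - x(i - 1, 2);
        double an = std::sqrt(ax * ax + ay * ay + az * az);
        if (an < 1e-12) { crank = false; }
        else {
          ax /= an; ay /= an; az /= an;
          double vx = x(i, 0) - x(i - 1, 0);
          double vy = x(i, 1) - x(i - 1, 1);
          double vz = x(i, 2) - x(i - 1, 2);
          double theta = 2.0 * M_PI * unif_rand();
          double ct = std::cos(theta), st = std::sin(theta);
          double dot = ax * vx + ay * vy + az * vz;
          double rx = vx * ct + (ay * vz - az * vy) * st + ax * dot * (1 - ct);
          double ry = vy * ct + (az * vx - ax * vz) * st + ay * dot * (1 - ct);
          double rz = vz * ct + (ax * vy - ay * vx) * st + az * dot * (1 - ct);
          nx = x(i - 1, 0) + rx; ny = x(i - 1, 1) + ry; nz = x(i - 1, 2) + rz;
        }
      }
      if (!crank) {
        nx = x(i, 0) + max_disp * (2.0 * unif_rand() - 1.0);
        ny = x(i, 1) + max_disp * (2.0 * unif_rand() - 1.0);
        nz = x(i, 2) + max_disp * (2.0 * unif_rand() - 1.0);
      }
      ++attempted;
      bool overlap_new = false, overlap_old = false;
      double e_old = bead_energy(x, i, x(i, 0), x(i, 1), x(i, 2), bond_k,
                                 bond_l0, K_now, cutoff2, hardcore2,
                                 excluded_volume, overlap_old);
      double e_new = bead_energy(x, i, nx, ny, nz, bond_k, bond_l0, K_now,
                                 cutoff2, hardcore2, excluded_volume,
                                 overlap_new);
      if (overlap_new) continue;
      double de = e_new - e_old;
      if (de <= 0.0 || unif_rand() < std::exp(-de)) {
        x(i, 0) = nx; x(i, 1) = ny; x(i, 2) = nz;
        energy += de;
        ++accepted;
      }
    }
  }
  double recomputed = NA_REAL;
  if (recheck_energy)
    recomputed = polymer_total_energy(x, bond_k, bond_l0, K, cutoff,
                                      hardcore, excluded_volume);
  return List::create(_["coords"] = x, _["energy"] = energy,
                      _["recomputed_energy"] = recomputed,
                      _["acceptance_rate"] =
                          (double)accepted / (double)attempted);
}
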