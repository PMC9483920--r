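// Grand-canonical Metropolis Monte Carlo for the square-well-linear SALR
// fluid, either confined between concentric hard spherical walls or in a
// periodic cubic box.  Cell-list neighbor search (cell edge >= kappa*sigma);
// energies tracked incrementally and recomputed by brute force for the
// bookkeeping check.  All randomness comes from R's RNG so runs are
// reproducible from set.seed().
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double eps;    // well depth (0 => pure hard spheres)
  double zeta;   // repulsion strength
  double lam;    // well range / sigma
  double kappa;  // repulsion range / sigma
  double lam2, kap2;
  bool ideal;    // ideal gas: no pair interactions at all (walls only)
};

struct Sim {
  // geometry: 0 = shell (hard walls), 1 = periodic cube
  int geom;
  double R_inn, R_out, L;
  double R_inn3, R_out3;
  Params par;
  double beta, z, V; // V = volume paired with insertion proposals

  std::vector<double> x, y, z_;
  // cell list (cell edge >= kappa/reach; neighbor scan over +-reach cells)
  int nc;            // cells per dimension
  int reach;         // neighbor shells needed to cover the kappa cutoff
  double cell_w, lo; // cell width, lower corner of the covered cube
  std::vector<std::vector<int>> cells;
  std::vector<int> pcell;

  int ncell_index(double px, double py, double pz) const {
    int ix = (int)std::floor((px - lo) / cell_w);
    int iy = (int)std::floor((py - lo) / cell_w);
    int iz = (int)std::floor((pz - lo) / cell_w);
    if (ix < 0) ix = 0; if (ix >= nc) ix = nc - 1;
    if (iy < 0) iy = 0; if (iy >= nc) iy = nc - 1;
    if (iz < 0) iz = 0; if (iz >= nc) iz = nc - 1;
    return (ix * nc + iy) * nc + iz;
  }

  void cells_init() {
    double span = (geom == 0) ? 2.0 * R_out : L;
    lo = (geom == 0) ? -R_out : 0.0;
    // target cell edge kappa/2: scanning +-2 cells covers the cutoff while
    // sampling ~40% less volume than kappa-sized cells with +-1
    nc = (int)std::floor(2.0 * span / par.kappa);
    if (nc < 1) nc = 1;
    cell_w = span / nc;
    reach = (int)std::ceil(par.kappa / cell_w);
    // periodic wrap double-counts a cell when the scan spans the whole box
    if (geom == 1 && 2 * reach + 1 > nc) nc = 1;
    if (nc == 1) { cell_w = span; reach = 0; }
    cells.assign((size_t)nc * nc * nc, {});
    pcell.assign(x.size(), -1);
    for (size_t i = 0; i < x.size(); ++i) {
      int c = ncell_index(x[i], y[i], z_[i]);
      cells[c].push_back((int)i);
      pcell[i] = c;
    }
  }

  void cell_remove(int i) {
    std::vector<int>& v = cells[pcell[i]];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); break; }
  }
  void cell_add(int i, double px, double py, double pz) {
    int c = ncell_index(px, py, pz);
    cells[c].push_back(i);
    pcell[i] = c;
  }

  double dist2(double ax, double ay, double az,
               double bx, double by, double bz) const {
    double dx = ax - bx, dy = ay - by, dz = az - bz;
    if (geom == 1) {
      dx -= L * std::round(dx / L);
      dy -= L * std::round(dy / L);
      dz -= L * std::round(dz / L);
    }
    return dx * dx + dy * dy + dz * dz;
  }

  // pair energy from squared distance; +Inf on core overlap
  double upair2(double d2) const {
    if (d2 < 1.0) return R_PosInf;
    if (d2 < par.lam2) return -par.eps;
    if (d2 < par.kap2) return par.eps * par.zeta * (par.kappa - std::sqrt(d2));
    return 0.0;
  }

  // interaction energy of a point with all particles except `excl`
  double energy_at(double px, double py, double pz, int excl) const {
    if (par.ideal) return 0.0;
    double u = 0.0;
    if (nc == 1) { // single cell: plain loop over everyone
      for (size_t j = 0; j < x.size(); ++j) {
        if ((int)j == excl) continue;
        double d2 = dist2(px, py, pz, x[j], y[j], z_[j]);
        if (d2 < 1.0) return R_PosInf;
        u += upair2(d2);
      }
      return u;
    }
    int icx = (int)std::floor((px - lo) / cell_w);
    int icy = (int)std::floor((py - lo) / cell_w);
    int icz = (int)std::floor((pz - lo) / cell_w);
    for (int ax = icx - reach; ax <= icx + reach; ++ax) {
      int wx = ax;
      if (geom == 1) { wx = (ax % nc + nc) % nc; }
      else if (wx < 0 || wx >= nc) continue;
      for (int ay = icy - reach; ay <= icy + reach; ++ay) {
        int wy = ay;
        if (geom == 1) { wy = (ay % nc + nc) % nc; }
        else if (wy < 0 || wy >= nc) continue;
        for (int az = icz - reach; az <= icz + reach; ++az) {
          int wz = az;
          if (geom == 1) { wz = (az % nc + nc) % nc; }
          else if (wz < 0 || wz >= nc) continue;
          const std::vector<int>& v = cells[(size_t)(wx * nc + wy) * nc + wz];
          for (size_t k = 0; k < v.size(); ++k) {
            int j = v[k];
            if (j == excl) continue;
            double d2 = dist2(px, py, pz, x[j], y[j], z_[j]);
            if (d2 < 1.0) return R_PosInf;
            double uj = upair2(d2);
            u += uj;
          }
        }
      }
    }
    return u;
  }

  bool in_shell(double px, double py, double pz) const {
    double r2 = px * px + py * py + pz * pz;
    return r2 >= R_inn * R_inn && r2 <= R_out * R_out;
  }

  double brute_energy() const {
    if (par.ideal) return 0.0;
    double u = 0.0;
    size_t n = x.size();
    for (size_t i = 0; i + 1 < n; ++i)
      for (size_t j = i + 1; j < n; ++j) {
        double d2 = dist2(x[i], y[i], z_[i], x[j], y[j], z_[j]);
        double uij = upair2(d2);
        if (uij == R_PosInf) return R_PosInf;
        u += uij;
      }
    return u;
  }
};

} // namespace

// [[Rcpp::export]]
List gcmc_run_cpp(NumericMatrix init_pos,
                  double eps, double zeta, double lam, double kappa,
                  double T_star, double mu_star,
                  int geometry, double R_inn, double R_out, double box_L,
                  double p_displacement, double delta,
                  double n_steps, double sample_interval, double traj_interval,
                  bool ideal_gas) {
  RNGScope rngscope;
  Sim s;
  s.geom = geometry;
  s.R_inn = R_inn; s.R_out = R_out; s.L = box_L;
  s.R_inn3 = R_inn * R_inn * R_inn;
  s.R_out3 = R_out * R_out * R_out;
  s.par.eps = eps; s.par.zeta = zeta; s.par.lam = lam; s.par.kappa = kappa;
  s.par.lam2 = lam * lam; s.par.kap2 = kappa * kappa;
  s.par.ideal = ideal_gas;
  s.beta = 1.0 / T_star;
  s.z = std::exp(mu_star / T_star);
  s.V = (geometry == 0)
          ? (4.0 * M_PI / 3.0) * (s.R_out3 - s.R_inn3)
          : box_L * box_L * box_L;

  int n0 = init_pos.nrow();
  s.x.reserve(n0 + 64); s.y.reserve(n0 + 64); s.z_.reserve(n0 + 64);
  for (int i = 0; i < n0; ++i) {
    s.x.push_back(init_pos(i, 0));
    s.y.push_back(init_pos(i, 1));
    s.z_.push_back(init_pos(i, 2));
  }
  s.cells_init();

  double U = s.brute_energy();
  if (U == R_PosInf) stop("initial configuration has overlapping particles");

  long long steps = (long long)n_steps;
  long long samp = sample_interval > 0 ? (long long)sample_interval : 0;
  long long trji = traj_interval > 0 ? (long long)traj_interval : 0;

  std::vector<double> log_step, log_N, log_U;
  List traj;
  std::vector<NumericMatrix> traj_frames;
  long long acc_disp = 0, try_disp = 0, acc_ins = 0, try_ins = 0,
            acc_del = 0, try_del = 0;

  for (long long step = 1; step <= steps; ++step) {
    double u0 = unif_rand();
    int N = (int)s.x.size();
    if (u0 < p_displacement) {
      ++try_disp;
      if (N > 0) {
        int i = (int)(unif_rand() * N);
        if (i == N) i = N - 1;
        double nx = s.x[i] + delta * (2.0 * unif_rand() - 1.0);
        double ny = s.y[i] + delta * (2.0 * unif_rand() - 1.0);
        double nz = s.z_[i] + delta * (2.0 * unif_rand() - 1.0);
        bool ok;
        if (s.geom == 0) ok = s.in_shell(nx, ny, nz);
        else {
          ok = true;
          nx -= s.L * std::floor(nx / s.L);
          ny -= s.L * std::floor(ny / s.L);
          nz -= s.L * std::floor(nz / s.L);
        }
        if (ok) {
          double uold = s.energy_at(s.x[i], s.y[i], s.z_[i], i);
          double unew = s.energy_at(nx, ny, nz, i);
          double dU = unew - uold;
          if (unew != R_PosInf &&
              (dU <= 0.0 || unif_rand() < std::exp(-s.beta * dU))) {
            s.cell_remove(i);
            s.x[i] = nx; s.y[i] = ny; s.z_[i] = nz;
            s.cell_add(i, nx, ny, nz);
            U += dU;
            ++acc_disp;
          }
        }
      }
    } else if (unif_rand() < 0.5) {
      // insertion
      ++try_ins;
      double nx, ny, nz;
      if (s.geom == 0) {
        // uniform in the shell: radius by inverse CDF, direction isotropic
        double r3 = s.R_inn3 + unif_rand() * (s.R_out3 - s.R_inn3);
        double r = std::cbrt(r3);
        double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
        double g = std::sqrt(gx * gx + gy * gy + gz * gz);
        while (g < 1e-12) {
          gx = norm_rand(); gy = norm_rand(); gz = norm_rand();
          g = std::sqrt(gx * gx + gy * gy + gz * gz);
        }
        nx = r * gx / g; ny = r * gy / g; nz = r * gz / g;
      } else {
        nx = s.L * unif_rand(); ny = s.L * unif_rand(); nz = s.L * unif_rand();
      }
      double dU = s.energy_at(nx, ny, nz, -1);
      if (dU != R_PosInf) {
        double arg = s.z * s.V / (N + 1.0) * std::exp(-s.beta * dU);
        if (arg >= 1.0 || unif_rand() < arg) {
          s.x.push_back(nx); s.y.push_back(ny); s.z_.push_back(nz);
          s.pcell.push_back(-1);
          s.cell_add(N, nx, ny, nz);
          U += dU;
          ++acc_ins;
        }
      }
    } else {
      // deletion
      ++try_del;
      if (N > 0) {
        int i = (int)(unif_rand() * N);
        if (i == N) i = N - 1;
        double ui = s.energy_at(s.x[i], s.y[i], s.z_[i], i);
        double arg = N / (s.z * s.V) * std::exp(s.beta * ui);
        if (arg >= 1.0 || unif_rand() < arg) {
          s.cell_remove(i);
          int last = N - 1;
          if (i != last) {
            // move the last particle into slot i, fixing its cell entry
            s.cell_remove(last);
            s.x[i] = s.x[last]; s.y[i] = s.y[last]; s.z_[i] = s.z_[last];
            s.cell_add(i, s.x[i], s.y[i], s.z_[i]);
          }
          s.x.pop_back(); s.y.pop_back(); s.z_.pop_back();
          s.pcell.pop_back();
          U -= ui;
          ++acc_del;
        }
      }
    }

    if (samp > 0 && step % samp == 0) {
      log_step.push_back((double)step);
      log_N.push_back((double)s.x.size());
      log_U.push_back(U);
    }
    if (trji > 0 && step % trji == 0) {
      int n = (int)s.x.size();
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) {
        fr(i, 0) = s.x[i]; fr(i, 1) = s.y[i]; fr(i, 2) = s.z_[i];
      }
      traj_frames.push_back(fr);
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  int n = (int)s.x.size();
  NumericMatrix fin(n, 3);
  for (int i = 0; i < n; ++i) {
    fin(i, 0) = s.x[i]; fin(i, 1) = s.y[i]; fin(i, 2) = s.z_[i];
  }
  List tlist(traj_frames.size());
  for (size_t i = 0; i < traj_frames.size(); ++i) tlist[i] = traj_frames[i];

  return List::create(
    _["positions"] = fin,
    _["U"] = U,
    _["U_recomputed"] = s.brute_energy(),
    _["log_step"] = log_step,
    _["log_N"] = log_N,
    _["log_U"] = log_U,
    _["trajectory"] = tlist,
    _["acc"] = NumericVector::create(
      _["disp_try"] = (double)try_disp, _["disp_acc"] = (double)acc_disp,
      _["ins_try"] = (double)try_ins, _["ins_acc"] = (double)acc_ins,
      _["del_try"] = (double)try_del, _["del_acc"] = (double)acc_del));
}

// Brute-force total energy (shell geometry or periodic box), used as the
// reference for the incremental bookkeeping and by analysis code on
// configurations too large for dist().
// [[Rcpp::export]]
double total_energy_cpp(NumericMatrix pos, double eps, double zeta,
                        double lam, double kappa, int geometry, double box_L) {
  Sim s;
  s.geom = geometry; s.L = box_L;
  s.par.eps = eps; s.par.zeta = zeta; s.par.lam = lam; s.par.kappa = kappa;
  s.par.lam2 = lam * lam; s.par.kap2 = kappa * kappa;
  s.par.ideal = false;
  int n = pos.nrow();
  s.x.resize(n); s.y.resize(n); s.z_.resize(n);
  for (int i = 0; i < n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z_[i] = pos(i, 2);
  }
  return s.brute_energy();
}

// Minimum-image pair distances below a cutoff (periodic cube), as a flat
// vector; used for distance histograms of bulk configurations.
// [[Rcpp::export]]
NumericVector pair_distances_cpp(NumericMatrix pos, double cutoff,
                                 int geometry, double box_L) {
  int n = pos.nrow();
  std::vector<double> out;
  double c2 = cutoff * cutoff;
  for (int i = 0; i + 1 < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (geometry == 1) {
        dx -= box_L * std::round(dx / box_L);
        dy -= box_L * std::round(dy / box_L);
        dz -= box_L * std::round(dz / box_L);
      }
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) out.push_back(std::sqrt(d2));
    }
  return NumericVector(out.begin(), out.end());
}
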