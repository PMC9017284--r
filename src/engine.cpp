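// Target function and simulated-annealing pose search for restrained
// ligand docking. The pose parameter vector is
//   [tx, ty, tz, rx, ry, rz, torsion_1 .. torsion_k]
// with (rx,ry,rz) a rotation vector (Rodrigues) applied after the torsions.
//
// The "problem" list is compiled on the R side (see compile_problem):
//   lig0        natoms x 3 local ligand coordinates
//   lig_rad     natoms scaled hard-sphere radii
//   grp_idx     1-based atom indices of proton groups, concatenated
//   grp_off     ngroups+1 offsets into grp_idx (1-based, R style)
//   tor_axis    k x 2 atom indices (axis a->b)
//   tor_idx/tor_off  moving-atom index lists per torsion
//   methyl_xyz  M x 3 receptor methyl pseudoatom coordinates
//   rec_xyz     K x 3 receptor clash atoms, rec_rad scaled radii
//   r_type      per restraint: 1 upper(inter) 2 lower(inter) 3 upper(intra) 4 lower(intra)
//   r_bound     bounds (Angstrom)
//   r_lgrp      ligand group index (1-based)
//   r_partner/r_poff  candidate methyl indices per restraint (inter), or
//                     single ligand group index (intra)
//   weights     c(upper, lower, clash)
//   center      3-vector pocket center (annealing start box)

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double gauss() {
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

struct Problem {
  NumericMatrix lig0, methyl, rec;
  NumericVector lig_rad, rec_rad, bound, weights, center;
  IntegerVector grp_idx, grp_off, tor_axis, tor_idx, tor_off;
  IntegerVector r_type, r_lgrp, r_partner, r_poff;
  int natoms, ngrp, ntor, nres;
  // flat copies for fast access
  std::vector<double> lx0, ly0, lz0, mx, my, mz, rx, ry, rz, rrad, lrad;
  // cell list (CSR layout) over the (static) receptor atoms
  double gx0, gy0, gz0, gcell;
  int gnx, gny, gnz;
  std::vector<int> cell_off, cell_idx;
  void build_flat() {
    int n = lig0.nrow();
    lx0.resize(n); ly0.resize(n); lz0.resize(n); lrad.resize(n);
    for (int i = 0; i < n; ++i) {
      lx0[i] = lig0(i,0); ly0[i] = lig0(i,1); lz0[i] = lig0(i,2);
      lrad[i] = lig_rad[i];
    }
    int M = methyl.nrow();
    mx.resize(M); my.resize(M); mz.resize(M);
    for (int k = 0; k < M; ++k) { mx[k]=methyl(k,0); my[k]=methyl(k,1); mz[k]=methyl(k,2); }
    int K = rec.nrow();
    rx.resize(K); ry.resize(K); rz.resize(K); rrad.resize(K);
    for (int k = 0; k < K; ++k) {
      rx[k]=rec(k,0); ry[k]=rec(k,1); rz[k]=rec(k,2); rrad[k]=rec_rad[k];
    }
  }
  void build_grid() {
    gcell = 3.0;
    int K = rec.nrow();
    if (K == 0) {
      gnx = gny = gnz = 1; cell_off.assign(2, 0); cell_idx.clear(); return;
    }
    double xmin = rx[0], xmax = rx[0], ymin = ry[0], ymax = ry[0],
           zmin = rz[0], zmax = rz[0];
    for (int k = 1; k < K; ++k) {
      xmin = std::min(xmin, rx[k]); xmax = std::max(xmax, rx[k]);
      ymin = std::min(ymin, ry[k]); ymax = std::max(ymax, ry[k]);
      zmin = std::min(zmin, rz[k]); zmax = std::max(zmax, rz[k]);
    }
    gx0 = xmin; gy0 = ymin; gz0 = zmin;
    gnx = std::max(1, (int)((xmax - xmin) / gcell) + 1);
    gny = std::max(1, (int)((ymax - ymin) / gcell) + 1);
    gnz = std::max(1, (int)((zmax - zmin) / gcell) + 1);
    size_t nc = (size_t)gnx * gny * gnz;
    std::vector<int> count(nc, 0), cidx(K);
    for (int k = 0; k < K; ++k) {
      int ix = std::min(gnx - 1, std::max(0, (int)((rx[k] - gx0) / gcell)));
      int iy = std::min(gny - 1, std::max(0, (int)((ry[k] - gy0) / gcell)));
      int iz = std::min(gnz - 1, std::max(0, (int)((rz[k] - gz0) / gcell)));
      cidx[k] = (int)((size_t)(ix * gny + iy) * gnz + iz);
      count[cidx[k]]++;
    }
    cell_off.assign(nc + 1, 0);
    for (size_t c = 0; c < nc; ++c) cell_off[c + 1] = cell_off[c] + count[c];
    cell_idx.resize(K);
    std::vector<int> cur(cell_off.begin(), cell_off.end() - 1);
    for (int k = 0; k < K; ++k) cell_idx[cur[cidx[k]]++] = k;
  }
  explicit Problem(const List& p)
      : lig0(as<NumericMatrix>(p["lig0"])),
        methyl(as<NumericMatrix>(p["methyl_xyz"])),
        rec(as<NumericMatrix>(p["rec_xyz"])),
        lig_rad(as<NumericVector>(p["lig_rad"])),
        rec_rad(as<NumericVector>(p["rec_rad"])),
        bound(as<NumericVector>(p["r_bound"])),
        weights(as<NumericVector>(p["weights"])),
        center(as<NumericVector>(p["center"])),
        grp_idx(as<IntegerVector>(p["grp_idx"])),
        grp_off(as<IntegerVector>(p["grp_off"])),
        tor_axis(as<IntegerVector>(p["tor_axis"])),
        tor_idx(as<IntegerVector>(p["tor_idx"])),
        tor_off(as<IntegerVector>(p["tor_off"])),
        r_type(as<IntegerVector>(p["r_type"])),
        r_lgrp(as<IntegerVector>(p["r_lgrp"])),
        r_partner(as<IntegerVector>(p["r_partner"])),
        r_poff(as<IntegerVector>(p["r_poff"])) {
    natoms = lig0.nrow();
    ngrp = grp_off.size() - 1;
    ntor = tor_off.size() - 1;
    nres = r_type.size();
    build_flat();
    build_grid();
  }
};

// ligand coordinates for a pose parameter vector
void pose_coords(const Problem& pb, const double* par,
                 std::vector<double>& x, std::vector<double>& y,
                 std::vector<double>& z) {
  int n = pb.natoms;
  x.resize(n); y.resize(n); z.resize(n);
  for (int i = 0; i < n; ++i) { x[i] = pb.lx0[i]; y[i] = pb.ly0[i]; z[i] = pb.lz0[i]; }
  // torsions: rotate the moving set around axis a->b
  for (int t = 0; t < pb.ntor; ++t) {
    double ang = par[6 + t];
    if (ang == 0.0) continue;
    int a = pb.tor_axis[2 * t] - 1, b = pb.tor_axis[2 * t + 1] - 1;
    double ax = x[b] - x[a], ay = y[b] - y[a], az = z[b] - z[a];
    double nrm = std::sqrt(ax * ax + ay * ay + az * az);
    if (nrm < 1e-12) continue;
    ax /= nrm; ay /= nrm; az /= nrm;
    double c = std::cos(ang), s = std::sin(ang);
    for (int m = pb.tor_off[t]; m < pb.tor_off[t + 1]; ++m) {
      int i = pb.tor_idx[m - 1] - 1;  // tor_off is 1-based R style
      double px = x[i] - x[a], py = y[i] - y[a], pz = z[i] - z[a];
      double dot = ax * px + ay * py + az * pz;
      double cx = ay * pz - az * py, cy = az * px - ax * pz,
             cz = ax * py - ay * px;
      x[i] = x[a] + px * c + cx * s + ax * dot * (1 - c);
      y[i] = y[a] + py * c + cy * s + ay * dot * (1 - c);
      z[i] = z[a] + pz * c + cz * s + az * dot * (1 - c);
    }
  }
  // global rotation (Rodrigues) about the ligand centroid, then translation
  double cx0 = 0, cy0 = 0, cz0 = 0;
  for (int i = 0; i < n; ++i) { cx0 += x[i]; cy0 += y[i]; cz0 += z[i]; }
  cx0 /= n; cy0 /= n; cz0 /= n;
  double rx = par[3], ry = par[4], rz = par[5];
  double th = std::sqrt(rx * rx + ry * ry + rz * rz);
  double ux = 0, uy = 0, uz = 1, c = 1, s = 0;
  if (th > 1e-12) { ux = rx / th; uy = ry / th; uz = rz / th;
                    c = std::cos(th); s = std::sin(th); }
  for (int i = 0; i < n; ++i) {
    double px = x[i] - cx0, py = y[i] - cy0, pz = z[i] - cz0;
    double dot = ux * px + uy * py + uz * pz;
    double vx = uy * pz - uz * py, vy = uz * px - ux * pz,
           vz = ux * py - uy * px;
    x[i] = cx0 + px * c + vx * s + ux * dot * (1 - c) + par[0];
    y[i] = cy0 + py * c + vy * s + uy * dot * (1 - c) + par[1];
    z[i] = cz0 + pz * c + vz * s + uz * dot * (1 - c) + par[2];
  }
}

void group_centroids(const Problem& pb, const std::vector<double>& x,
                     const std::vector<double>& y, const std::vector<double>& z,
                     std::vector<double>& gx, std::vector<double>& gy,
                     std::vector<double>& gz) {
  gx.assign(pb.ngrp, 0); gy.assign(pb.ngrp, 0); gz.assign(pb.ngrp, 0);
  for (int g = 0; g < pb.ngrp; ++g) {
    int lo = pb.grp_off[g], hi = pb.grp_off[g + 1];
    for (int m = lo; m < hi; ++m) {
      int i = pb.grp_idx[m - 1] - 1;
      gx[g] += x[i]; gy[g] += y[i]; gz[g] += z[i];
    }
    double cnt = hi - lo;
    gx[g] /= cnt; gy[g] /= cnt; gz[g] /= cnt;
  }
}

// energy components; if viol/dist non-null, fill per-restraint values
void energy_components(const Problem& pb, const double* par, double* up_sum,
                       double* lo_sum, double* cl_sum,
                       std::vector<double>* viol = nullptr,
                       std::vector<double>* dist = nullptr) {
  std::vector<double> x, y, z, gx, gy, gz;
  pose_coords(pb, par, x, y, z);
  group_centroids(pb, x, y, z, gx, gy, gz);
  double wu = pb.weights[0], wl = pb.weights[1], wc = pb.weights[2];
  double up = 0, lo = 0, cl = 0;
  if (viol) { viol->assign(pb.nres, 0.0); dist->assign(pb.nres, 0.0); }
  for (int r = 0; r < pb.nres; ++r) {
    int g = pb.r_lgrp[r] - 1;
    double d;
    if (pb.r_type[r] <= 2) {  // intermolecular: r^-6 sum over candidates
      double s6 = 0;
      for (int m = pb.r_poff[r]; m < pb.r_poff[r + 1]; ++m) {
        int k = pb.r_partner[m - 1] - 1;
        double dx = gx[g] - pb.mx[k], dy = gy[g] - pb.my[k],
               dz = gz[g] - pb.mz[k];
        double d2 = dx * dx + dy * dy + dz * dz;
        s6 += 1.0 / (d2 * d2 * d2);
      }
      d = std::pow(s6, -1.0 / 6.0);
    } else {  // intraligand
      int g2 = pb.r_partner[pb.r_poff[r] - 1] - 1;
      double dx = gx[g] - gx[g2], dy = gy[g] - gy[g2], dz = gz[g] - gz[g2];
      d = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    double b = pb.bound[r], v = 0;
    if (pb.r_type[r] == 1 || pb.r_type[r] == 3) {
      if (d > b) { v = d - b; up += wu * v * v; }
    } else {
      if (d < b) { v = b - d; lo += wl * v * v; }
    }
    if (viol) { (*viol)[r] = v; (*dist)[r] = d; }
  }
  // hard-sphere repulsion, ligand atom vs receptor atom (cell list; the
  // cell size exceeds every scaled contact distance)
  if (!pb.rx.empty()) {
    for (int i = 0; i < pb.natoms; ++i) {
      int ix = std::min(pb.gnx - 1, std::max(0, (int)((x[i] - pb.gx0) / pb.gcell)));
      int iy = std::min(pb.gny - 1, std::max(0, (int)((y[i] - pb.gy0) / pb.gcell)));
      int iz = std::min(pb.gnz - 1, std::max(0, (int)((z[i] - pb.gz0) / pb.gcell)));
      for (int ax = std::max(0, ix - 1); ax <= std::min(pb.gnx - 1, ix + 1); ++ax)
        for (int ay = std::max(0, iy - 1); ay <= std::min(pb.gny - 1, iy + 1); ++ay) {
          int az0 = std::max(0, iz - 1), az1 = std::min(pb.gnz - 1, iz + 1);
          size_t base = (size_t)(ax * pb.gny + ay) * pb.gnz;
          int lo = pb.cell_off[base + az0], hi = pb.cell_off[base + az1 + 1];
          for (int c = lo; c < hi; ++c) {
            int k = pb.cell_idx[c];
            double rmin = pb.lrad[i] + pb.rrad[k];
            double dx = x[i] - pb.rx[k], dy = y[i] - pb.ry[k],
                   dz = z[i] - pb.rz[k];
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < rmin * rmin) {
              double v = rmin - std::sqrt(d2);
              cl += wc * v * v;
            }
          }
        }
    }
  }
  *up_sum = up; *lo_sum = lo; *cl_sum = cl;
}

double energy_total(const Problem& pb, const double* par) {
  double u, l, c;
  energy_components(pb, par, &u, &l, &c);
  return u + l + c;
}

}  // namespace

// [[Rcpp::export]]
double cpp_pose_energy(NumericVector par, List prob) {
  Problem pb(prob);
  return energy_total(pb, REAL(par));
}

// [[Rcpp::export]]
List cpp_pose_report(NumericVector par, List prob) {
  Problem pb(prob);
  double u, l, c;
  std::vector<double> viol, dist;
  energy_components(pb, REAL(par), &u, &l, &c, &viol, &dist);
  return List::create(_["upper_violation_sum"] = u,
                      _["lower_violation_sum"] = l, _["clash_sum"] = c,
                      _["total"] = u + l + c,
                      _["violations"] = NumericVector(viol.begin(), viol.end()),
                      _["distances"] = NumericVector(dist.begin(), dist.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_ligand_coords(NumericVector par, List prob) {
  Problem pb(prob);
  std::vector<double> x, y, z;
  pose_coords(pb, REAL(par), x, y, z);
  NumericMatrix out(pb.natoms, 3);
  for (int i = 0; i < pb.natoms; ++i) {
    out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i];
  }
  return out;
}

// Multi-start simulated annealing with geometric cooling. Deterministic for
// a given seed: per-restart RNG streams are seeded seed*1e6 + restart.
// [[Rcpp::export]]
List cpp_anneal(List prob, int n_restarts, int n_steps, double t_start,
                double t_end, double step_trans, double step_rot,
                double step_tor, double box_radius, double seed) {
  Problem pb(prob);
  int npar = 6 + pb.ntor;
  std::vector<double> best(npar, 0.0);
  double best_e = R_PosInf;
  double cool = (n_steps > 1) ? std::pow(t_end / t_start, 1.0 / (n_steps - 1))
                              : 1.0;
  for (int rs = 0; rs < n_restarts; ++rs) {
    RNG rng(static_cast<uint64_t>(seed) * 1000003ULL +
            static_cast<uint64_t>(rs));
    std::vector<double> cur(npar), trial(npar);
    for (int k = 0; k < 3; ++k)
      cur[k] = pb.center[k] + (rng.unif() * 2 - 1) * box_radius;
    // random rotation vector: random direction, angle in [0, pi]
    double gx = rng.gauss(), gy = rng.gauss(), gz = rng.gauss();
    double gn = std::sqrt(gx * gx + gy * gy + gz * gz) + 1e-12;
    double ang = rng.unif() * M_PI;
    cur[3] = gx / gn * ang; cur[4] = gy / gn * ang; cur[5] = gz / gn * ang;
    for (int t = 0; t < pb.ntor; ++t) cur[6 + t] = (rng.unif() * 2 - 1) * M_PI;
    double cur_e = energy_total(pb, cur.data());
    double loc_best_e = cur_e;
    std::vector<double> loc_best = cur;
    double temp = t_start;
    for (int step = 0; step < n_steps; ++step) {
      trial = cur;
      double frac = 0.2 + 0.8 * temp / t_start;  // shrink moves as we cool
      double u = rng.unif();
      if (u < 0.4) {
        for (int k = 0; k < 3; ++k)
          trial[k] += rng.gauss() * step_trans * frac;
      } else if (u < 0.8 || pb.ntor == 0) {
        for (int k = 3; k < 6; ++k)
          trial[k] += rng.gauss() * step_rot * frac;
      } else {
        int t = static_cast<int>(rng.unif() * pb.ntor);
        if (t >= pb.ntor) t = pb.ntor - 1;
        trial[6 + t] += rng.gauss() * step_tor * frac;
      }
      double e = energy_total(pb, trial.data());
      if (e <= cur_e || rng.unif() < std::exp(-(e - cur_e) / temp)) {
        cur = trial; cur_e = e;
        if (e < loc_best_e) { loc_best_e = e; loc_best = cur; }
      }
      temp *= cool;
      if (loc_best_e <= 0.0) break;  // exact satisfaction: nothing to improve
    }
    if (loc_best_e < best_e) { best_e = loc_best_e; best = loc_best; }
    if (best_e <= 0.0) break;
  }
  return List::create(_["par"] = NumericVector(best.begin(), best.end()),
                      _["energy"] = best_e);
}
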