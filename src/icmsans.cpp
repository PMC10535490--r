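#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sinc(double x) {
  // sin(x)/x with the analytic q -> 0 limit
  if (std::fabs(x) < 1e-8) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

// Exact orientationally averaged Debye sum I(q) = sum_ij b_i b_j sinc(q r_ij)
// [[Rcpp::export]]
NumericVector cpp_debye_exact(NumericMatrix xyz, NumericVector b, NumericVector q) {
  const int n = xyz.nrow(), nq = q.size();
  NumericVector I(nq);
  double self = 0.0;
  for (int i = 0; i < n; ++i) self += b[i] * b[i];
  for (int k = 0; k < nq; ++k) I[k] = self;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double w = 2.0 * b[i] * b[j];
      for (int k = 0; k < nq; ++k) I[k] += w * sinc(q[k] * r);
    }
  }
  return I;
}

// b-weighted histogram of pair distances (i < j, weight 2 b_i b_j).
// Returns bin centers and accumulated weights; bins start at 0.
// [[Rcpp::export]]
List cpp_pair_histogram(NumericMatrix xyz, NumericVector b, double bin) {
  const int n = xyz.nrow();
  double rmax = 0.0;
  std::vector<double> w, wr, wabs;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r > rmax) rmax = r;
      size_t k = (size_t)(r / bin);
      if (k >= w.size()) { w.resize(k + 1, 0.0); wr.resize(k + 1, 0.0);
                           wabs.resize(k + 1, 0.0); }
      double ww = 2.0 * b[i] * b[j];
      w[k] += ww;
      wabs[k] += std::fabs(ww);
      wr[k] += std::fabs(ww) * r;
    }
  }
  int nb = (int)w.size();
  NumericVector centers(nb), weights(nb);
  for (int k = 0; k < nb; ++k) {
    // |w|-weighted mean distance per bin: second-order accurate vs centers
    centers[k] = wabs[k] > 0 ? wr[k] / wabs[k] : (k + 0.5) * bin;
    weights[k] = w[k];
  }
  double self = 0.0;
  for (int i = 0; i < n; ++i) self += b[i] * b[i];
  return List::create(_["r"] = centers, _["w"] = weights,
                      _["self"] = self, _["rmax"] = rmax);
}

// I(q) from a pair-distance histogram plus the self term.
// [[Rcpp::export]]
NumericVector cpp_debye_from_hist(NumericVector r, NumericVector w, double self,
                                  NumericVector q) {
  const int nb = r.size(), nq = q.size();
  NumericVector I(nq);
  for (int k = 0; k < nq; ++k) {
    double s = self;
    for (int m = 0; m < nb; ++m) s += w[m] * sinc(q[k] * r[m]);
    I[k] = s;
  }
  return I;
}

// Off-lattice 3D diffusion-limited aggregation with sticking probability 1.
// Monomers of radius `rad` random-walk from a launch sphere and freeze on
// first contact (centre distance <= 2 rad). Uses the R RNG.
// [[Rcpp::export]]
NumericMatrix cpp_dla_cluster(int n, double rad) {
  NumericMatrix out(n, 3);
  std::vector<double> X(n), Y(n), Z(n);
  X[0] = Y[0] = Z[0] = 0.0;
  double rmax = 0.0;               // radius of the cluster envelope
  const double d = 2.0 * rad;      // contact distance
  const double d2 = d * d;
  const double step = rad;         // walk step length

  // coarse occupancy grid for neighbour lookup
  const double cell = 2.0 * rad;
  std::vector<int> head;           // filled lazily below via rebuild
  auto cellIndex = [&](double x, double y, double z, int ncell, double half) {
    int ix = (int)((x + half) / cell), iy = (int)((y + half) / cell),
        iz = (int)((z + half) / cell);
    if (ix < 0) ix = 0; if (ix >= ncell) ix = ncell - 1;
    if (iy < 0) iy = 0; if (iy >= ncell) iy = ncell - 1;
    if (iz < 0) iz = 0; if (iz >= ncell) iz = ncell - 1;
    return (ix * ncell + iy) * ncell + iz;
  };

  std::vector<int> nxt(n, -1);
  double half = 0.0; int ncell = 0;
  auto rebuild = [&](int npl, double newhalf) {
    half = newhalf;
    ncell = (int)(2.0 * half / cell) + 1;
    head.assign((size_t)ncell * ncell * ncell, -1);
    for (int i = 0; i < npl; ++i) {
      int c = cellIndex(X[i], Y[i], Z[i], ncell, half);
      nxt[i] = head[c];
      head[c] = i;
    }
  };
  rebuild(1, 10.0 * rad + 10.0);

  for (int i = 1; i < n; ++i) {
    double rl = rmax + 5.0 * d;    // launch radius
    double rk = rl * 3.0 + 10.0 * d; // kill radius
    if (rl + d > half) rebuild(i, rk + 2.0 * cell);
    bool placed = false;
    while (!placed) {
      // random point on launch sphere
      double u = 2.0 * unif_rand() - 1.0;
      double ph = 2.0 * M_PI * unif_rand();
      double s = std::sqrt(1.0 - u * u);
      double x = rl * s * std::cos(ph), y = rl * s * std::sin(ph), z = rl * u;
      while (true) {
        double r2c = x * x + y * y + z * z;
        if (r2c > rk * rk) break;  // escaped: relaunch
        // unbiased step; far outside the cluster envelope the walker can
        // jump the whole gap to the envelope in one spherically symmetric
        // move without changing first-contact statistics
        double rc = std::sqrt(r2c);
        double len = std::max(step, rc - rmax - 2.0 * d);
        double uu = 2.0 * unif_rand() - 1.0;
        double pp = 2.0 * M_PI * unif_rand();
        double ss = std::sqrt(1.0 - uu * uu);
        double vx = len * ss * std::cos(pp), vy = len * ss * std::sin(pp),
               vz = len * uu;
        // long jumps are sized to end at least 2d clear of every monomer,
        // so only a short step can make contact: place the walker at its
        // exact first intersection with any contact sphere along the step,
        // which guarantees touching without overlap
        if (len == step) {
          int c0 = cellIndex(x, y, z, ncell, half);
          int iz0 = c0 % ncell, iy0 = (c0 / ncell) % ncell,
              ix0 = c0 / (ncell * ncell);
          int hit = -1; double tmin = 2.0;
          for (int ax = ix0 - 2; ax <= ix0 + 2; ++ax) {
            if (ax < 0 || ax >= ncell) continue;
            for (int ay = iy0 - 2; ay <= iy0 + 2; ++ay) {
              if (ay < 0 || ay >= ncell) continue;
              for (int az = iz0 - 2; az <= iz0 + 2; ++az) {
                if (az < 0 || az >= ncell) continue;
                for (int j = head[(ax * ncell + ay) * ncell + az]; j >= 0;
                     j = nxt[j]) {
                  // smallest t in [0,1] with |(p - c_j) + t v| = d
                  double wx = x - X[j], wy = y - Y[j], wz = z - Z[j];
                  double a2 = vx * vx + vy * vy + vz * vz;
                  double bq = wx * vx + wy * vy + wz * vz;
                  double cq = wx * wx + wy * wy + wz * wz - d2;
                  double disc = bq * bq - a2 * cq;
                  if (disc < 0.0) continue;
                  double t = (-bq - std::sqrt(disc)) / a2;
                  if (t >= 0.0 && t <= 1.0 && t < tmin) { tmin = t; hit = j; }
                }
              }
            }
          }
          if (hit >= 0) {
            X[i] = x + tmin * vx;
            Y[i] = y + tmin * vy;
            Z[i] = z + tmin * vz;
            double rn = std::sqrt(X[i] * X[i] + Y[i] * Y[i] + Z[i] * Z[i]);
            if (rn > rmax) rmax = rn;
            int c = cellIndex(X[i], Y[i], Z[i], ncell, half);
            nxt[i] = head[c];
            head[c] = i;
            placed = true;
            break;
          }
        }
        x += vx; y += vy; z += vz;
      }
    }
  }
  for (int i = 0; i < n; ++i) { out(i, 0) = X[i]; out(i, 1) = Y[i]; out(i, 2) = Z[i]; }
  return out;
}

// Hydration-shell surface sampling (Shrake-Rupley style): candidate points on
// a sphere of radius rad_i + t/2 around each atom are kept when not inside any
// other atom's sampling sphere; each kept point carries an equal share of its
// atom's mid-shell area times the shell thickness.
// [[Rcpp::export]]
List cpp_shell_points(NumericMatrix xyz, NumericVector radii, double thickness,
                      int npts) {
  const int n = xyz.nrow();
  const double t2 = thickness / 2.0;
  std::vector<double> px, py, pz, pv;
  const double ga = M_PI * (3.0 - std::sqrt(5.0)); // golden angle
  for (int i = 0; i < n; ++i) {
    double R = radii[i] + t2;
    double vol_per = 4.0 * M_PI * R * R * thickness / npts;
    for (int k = 0; k < npts; ++k) {
      double zz = 1.0 - 2.0 * (k + 0.5) / npts;
      double rr = std::sqrt(1.0 - zz * zz);
      double th = ga * k;
      double x = xyz(i, 0) + R * rr * std::cos(th);
      double y = xyz(i, 1) + R * rr * std::sin(th);
      double z = xyz(i, 2) + R * zz;
      bool buried = false;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double Rj = radii[j] + t2 - 1e-9;
        double dx = x - xyz(j, 0), dy = y - xyz(j, 1), dz = z - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { buried = true; break; }
      }
      if (!buried) { px.push_back(x); py.push_back(y); pz.push_back(z); pv.push_back(vol_per); }
    }
  }
  int m = (int)px.size();
  NumericMatrix pts(m, 3);
  NumericVector vol(m);
  for (int k = 0; k < m; ++k) {
    pts(k, 0) = px[k]; pts(k, 1) = py[k]; pts(k, 2) = pz[k]; vol[k] = pv[k];
  }
  return List::create(_["points"] = pts, _["volume"] = vol);
}

// For each row of A, the distance to the nearest row of B.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = 1e300;
    for (int j = 0; j < nb; ++j) {
      double dx = A(i, 0) - B(j, 0);
      double dy = A(i, 1) - B(j, 1);
      double dz = A(i, 2) - B(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static double chi2_scaled(const std::vector<double>& Im, NumericVector It,
                          NumericVector isig2, int nq, double* scale_out) {
  double num = 0.0, den = 0.0;
  for (int k = 0; k < nq; ++k) {
    num += Im[k] * It[k] * isig2[k];
    den += Im[k] * Im[k] * isig2[k];
  }
  double s = den > 0 ? num / den : 0.0;
  double c = 0.0;
  for (int k = 0; k < nq; ++k) {
    double d = s * Im[k] - It[k];
    c += d * d * isig2[k];
  }
  if (scale_out) *scale_out = s;
  return c / std::max(1, nq - 1);
}

// Simulated-annealing bead fit on a fixed lattice. Single-bead flips,
// Metropolis acceptance, energy = chi^2 (with free scale) + w_loose *
// (fraction of occupied beads with < 3 occupied neighbours).
// adj: 0-based adjacency list (R list of integer vectors).
// Uses the R RNG. Returns final occupancy and traces.
// [[Rcpp::export]]
List cpp_bead_anneal(NumericMatrix lattice, LogicalVector occ0, List adj,
                     NumericVector q, NumericVector I_target, NumericVector sigma,
                     double w_loose, double T0, double cool, int steps_per_T,
                     double T_min) {
  const int M = lattice.nrow(), nq = q.size();
  std::vector<char> occ(M);
  std::vector<int> nnb(M, 0); // occupied-neighbour counts
  std::vector<std::vector<int>> nb(M);
  for (int i = 0; i < M; ++i) {
    IntegerVector v = adj[i];
    nb[i] = std::vector<int>(v.begin(), v.end());
  }
  for (int i = 0; i < M; ++i) occ[i] = occ0[i] ? 1 : 0;
  for (int i = 0; i < M; ++i)
    if (occ[i]) for (int j : nb[i]) nnb[j]++;

  NumericVector isig2(nq);
  for (int k = 0; k < nq; ++k) isig2[k] = 1.0 / (sigma[k] * sigma[k]);

  // model intensity for unit scattering lengths
  std::vector<double> Im(nq, 0.0);
  {
    std::vector<int> occl;
    for (int i = 0; i < M; ++i) if (occ[i]) occl.push_back(i);
    int no = (int)occl.size();
    for (int k = 0; k < nq; ++k) Im[k] = no;
    for (int a = 0; a < no; ++a) {
      for (int b = a + 1; b < no; ++b) {
        int i = occl[a], j = occl[b];
        double dx = lattice(i, 0) - lattice(j, 0);
        double dy = lattice(i, 1) - lattice(j, 1);
        double dz = lattice(i, 2) - lattice(j, 2);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        for (int k = 0; k < nq; ++k) Im[k] += 2.0 * sinc(q[k] * r);
      }
    }
  }
  int n_occ = 0, n_loose = 0;
  for (int i = 0; i < M; ++i) if (occ[i]) { ++n_occ; if (nnb[i] < 3) ++n_loose; }

  double chi2 = chi2_scaled(Im, I_target, isig2, nq, nullptr);
  double E = chi2 + w_loose * (n_occ > 0 ? (double)n_loose / n_occ : 1.0);
  const double chi2_init = chi2;

  std::vector<double> dI(nq);
  double T = T0;
  int n_T = 0;
  while (T > T_min) {
    for (int s = 0; s < steps_per_T; ++s) {
      int k0 = (int)(unif_rand() * M);
      if (k0 >= M) k0 = M - 1;
      if (occ[k0] && n_occ <= 2) continue; // keep at least 2 beads
      double sgn = occ[k0] ? -1.0 : 1.0;
      // intensity change from flipping bead k0
      for (int k = 0; k < nq; ++k) dI[k] = 1.0;
      for (int i = 0; i < M; ++i) {
        if (!occ[i] || i == k0) continue;
        double dx = lattice(i, 0) - lattice(k0, 0);
        double dy = lattice(i, 1) - lattice(k0, 1);
        double dz = lattice(i, 2) - lattice(k0, 2);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        for (int k = 0; k < nq; ++k) dI[k] += 2.0 * sinc(q[k] * r);
      }
      std::vector<double> Im_new(nq);
      for (int k = 0; k < nq; ++k) Im_new[k] = Im[k] + sgn * dI[k];
      // looseness after the flip
      int n_occ_new = n_occ + (occ[k0] ? -1 : 1);
      std::vector<int> touched = nb[k0];
      touched.push_back(k0);
      occ[k0] = !occ[k0];
      for (int j : nb[k0]) nnb[j] += occ[k0] ? 1 : -1;
      int n_loose_new = 0;
      for (int i = 0; i < M; ++i) if (occ[i] && nnb[i] < 3) ++n_loose_new;
      double chi2_new = chi2_scaled(Im_new, I_target, isig2, nq, nullptr);
      double E_new = chi2_new +
        w_loose * (n_occ_new > 0 ? (double)n_loose_new / n_occ_new : 1.0);
      double dE = E_new - E;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / T)) {
        Im.swap(Im_new);
        n_occ = n_occ_new;
        n_loose = n_loose_new;
        chi2 = chi2_new;
        E = E_new;
      } else {
        // revert
        for (int j : nb[k0]) nnb[j] += occ[k0] ? -1 : 1;
        occ[k0] = !occ[k0];
      }
    }
    T *= cool;
    ++n_T;
  }
  double scale;
  chi2 = chi2_scaled(Im, I_target, isig2, nq, &scale);
  LogicalVector occ_out(M);
  for (int i = 0; i < M; ++i) occ_out[i] = occ[i] != 0;
  NumericVector Iout(nq);
  for (int k = 0; k < nq; ++k) Iout[k] = scale * Im[k];
  return List::create(_["occupied"] = occ_out, _["chi2"] = chi2,
                      _["chi2_init"] = chi2_init, _["scale"] = scale,
                      _["I_model"] = Iout, _["n_temperatures"] = n_T,
                      _["energy"] = E);
}
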