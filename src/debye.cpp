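#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Amplitude form factor of a homogeneous sphere of radius r at momentum
// transfer s: Phi(x) = 3 (sin x - x cos x) / x^3 with x = s*r.
static inline double sphere_ff(double x) {
  if (std::fabs(x) < 1e-5) return 1.0 - x * x / 10.0;
  return 3.0 * (std::sin(x) - x * std::cos(x)) / (x * x * x);
}

static inline double sinc(double x) {
  if (std::fabs(x) < 1e-8) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

// second derivative of sinc, for the bin-variance correction
static inline double sinc_dd(double x) {
  if (std::fabs(x) < 1e-4) return -1.0 / 3.0 + x * x / 10.0;
  return -std::sin(x) / x - 2.0 * std::cos(x) / (x * x) +
         2.0 * std::sin(x) / (x * x * x);
}

// Exact O(N^2) Debye sum: I(s) = Phi^2(s r0) * sum_ij g_i g_j sinc(s d_ij).
// [[Rcpp::export]]
NumericVector debye_exact_cpp(NumericMatrix xyz, NumericVector g,
                              double r0, NumericVector s) {
  const int n = xyz.nrow(), ns = s.size();
  NumericVector I(ns);
  std::vector<double> x(n), y(n), z(n), gv(n);
  for (int i = 0; i < n; ++i) {
    x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2); gv[i] = g[i];
  }
  double self = 0.0;
  for (int i = 0; i < n; ++i) self += gv[i] * gv[i];
  for (int k = 0; k < ns; ++k) I[k] = self;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double w = 2.0 * gv[i] * gv[j];
      for (int k = 0; k < ns; ++k) I[k] += w * sinc(s[k] * d);
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  for (int k = 0; k < ns; ++k) {
    const double ff = sphere_ff(s[k] * r0);
    I[k] *= ff * ff;
  }
  return I;
}

// Binned Debye sum: pair distances are accumulated into a histogram of the
// given bin width (representative distance = bin centre); the s = 0 limit and
// the self term are exact, so I(0) = (sum g)^2 regardless of binning.
// [[Rcpp::export]]
NumericVector debye_binned_cpp(NumericMatrix xyz, NumericVector g,
                               double r0, NumericVector s, double bin_width) {
  const int n = xyz.nrow(), ns = s.size();
  std::vector<double> x(n), y(n), z(n), gv(n);
  double gsum = 0.0, self = 0.0;
  for (int i = 0; i < n; ++i) {
    x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2); gv[i] = g[i];
    gsum += gv[i]; self += gv[i] * gv[i];
  }
  // upper bound on the pair distance from the bounding box diagonal
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    double p[3] = {x[i], y[i], z[i]};
    for (int a = 0; a < 3; ++a) {
      if (p[a] < lo[a]) lo[a] = p[a];
      if (p[a] > hi[a]) hi[a] = p[a];
    }
  }
  double diag = 0.0;
  for (int a = 0; a < 3; ++a) diag += (hi[a] - lo[a]) * (hi[a] - lo[a]);
  diag = std::sqrt(diag);
  const int nb = (int)(diag / bin_width) + 2;
  std::vector<double> hist(nb, 0.0), wabs(nb, 0.0), wd(nb, 0.0), wd2(nb, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)(d / bin_width);
      if (b >= nb) b = nb - 1;
      const double w = 2.0 * gv[i] * gv[j];
      hist[b] += w;
      const double aw = std::fabs(w);
      wabs[b] += aw;
      wd[b] += aw * d;
      wd2[b] += aw * d * d;
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  // per-bin mean distance and variance (|w|-weighted): evaluating sinc at
  // the bin mean with a half-variance curvature correction leaves only a
  // third-order binning error
  std::vector<double> deff(nb), dvar(nb);
  for (int b = 0; b < nb; ++b) {
    if (wabs[b] > 0) {
      deff[b] = wd[b] / wabs[b];
      dvar[b] = std::max(wd2[b] / wabs[b] - deff[b] * deff[b], 0.0);
    } else {
      deff[b] = (b + 0.5) * bin_width;
      dvar[b] = 0.0;
    }
  }
  NumericVector I(ns);
  for (int k = 0; k < ns; ++k) {
    const double sk = s[k];
    double acc;
    if (sk <= 0.0) {
      acc = gsum * gsum;        // exact forward limit
    } else {
      acc = self;
      for (int b = 0; b < nb; ++b) {
        if (hist[b] != 0.0) {
          const double xx = sk * deff[b];
          acc += hist[b] * (sinc(xx) +
                            0.5 * sk * sk * dvar[b] * sinc_dd(xx));
        }
      }
    }
    const double ff = sphere_ff(sk * r0);
    I[k] = acc * ff * ff;
  }
  return I;
}

// All (i, j) pairs with i < j and distance <= cutoff, as a CSR adjacency
// (both directions). Used for bead contact graphs (12 HCP contacts).
// [[Rcpp::export]]
List neighbors_within_cpp(NumericMatrix xyz, double cutoff) {
  const int n = xyz.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2); }
  // cell list on a grid of size cutoff
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int i = 0; i < n; ++i) {
    if (x[i] < lo[0]) lo[0] = x[i];
    if (y[i] < lo[1]) lo[1] = y[i];
    if (z[i] < lo[2]) lo[2] = z[i];
  }
  auto cell = [&](double v, double l) { return (int)((v - l) / cutoff); };
  int nx = 0, ny = 0, nz = 0;
  for (int i = 0; i < n; ++i) {
    nx = std::max(nx, cell(x[i], lo[0]) + 1);
    ny = std::max(ny, cell(y[i], lo[1]) + 1);
    nz = std::max(nz, cell(z[i], lo[2]) + 1);
  }
  std::vector<std::vector<int>> cells((size_t)nx * ny * nz);
  auto cid = [&](int cx, int cy, int cz) { return (size_t)(cx * ny + cy) * nz + cz; };
  for (int i = 0; i < n; ++i)
    cells[cid(cell(x[i], lo[0]), cell(y[i], lo[1]), cell(z[i], lo[2]))].push_back(i);
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    const int cx = cell(x[i], lo[0]), cy = cell(y[i], lo[1]), cz = cell(z[i], lo[2]);
    for (int ax = std::max(0, cx - 1); ax <= std::min(nx - 1, cx + 1); ++ax)
      for (int ay = std::max(0, cy - 1); ay <= std::min(ny - 1, cy + 1); ++ay)
        for (int az = std::max(0, cz - 1); az <= std::min(nz - 1, cz + 1); ++az)
          for (int j : cells[cid(ax, ay, az)]) {
            if (j <= i) continue;
            const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
            if (dx * dx + dy * dy + dz * dz <= c2) {
              adj[i].push_back(j);
              adj[j].push_back(i);
            }
          }
  }
  IntegerVector ptr(n + 1);
  int tot = 0;
  for (int i = 0; i < n; ++i) { ptr[i] = tot; tot += (int)adj[i].size(); }
  ptr[n] = tot;
  IntegerVector idx(tot);
  int k = 0;
  for (int i = 0; i < n; ++i)
    for (int j : adj[i]) idx[k++] = j;
  return List::create(_["ptr"] = ptr, _["idx"] = idx);
}

// For each query point, whether any reference point lies within cutoff.
// [[Rcpp::export]]
LogicalVector points_near_cpp(NumericMatrix query, NumericMatrix ref,
                              double cutoff) {
  const int nq = query.nrow(), nr = ref.nrow();
  const double c2 = cutoff * cutoff;
  LogicalVector out(nq);
  // cell list over reference points
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int i = 0; i < nr; ++i)
    for (int a = 0; a < 3; ++a) lo[a] = std::min(lo[a], ref(i, a));
  auto cell = [&](double v, int a) { return (int)((v - lo[a]) / cutoff); };
  int nc[3] = {1, 1, 1};
  for (int i = 0; i < nr; ++i)
    for (int a = 0; a < 3; ++a) nc[a] = std::max(nc[a], cell(ref(i, a), a) + 1);
  std::vector<std::vector<int>> cells((size_t)nc[0] * nc[1] * nc[2]);
  auto cid = [&](int cx, int cy, int cz) {
    return (size_t)(cx * nc[1] + cy) * nc[2] + cz;
  };
  for (int i = 0; i < nr; ++i)
    cells[cid(cell(ref(i, 0), 0), cell(ref(i, 1), 1), cell(ref(i, 2), 2))].push_back(i);
  for (int i = 0; i < nq; ++i) {
    bool hit = false;
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    const int cx = cell(qx, 0), cy = cell(qy, 1), cz = cell(qz, 2);
    for (int ax = std::max(0, cx - 1); ax <= std::min(nc[0] - 1, cx + 1) && !hit; ++ax)
      for (int ay = std::max(0, cy - 1); ay <= std::min(nc[1] - 1, cy + 1) && !hit; ++ay)
        for (int az = std::max(0, cz - 1); az <= std::min(nc[2] - 1, cz + 1) && !hit; ++az) {
          if (ax >= nc[0] || ay >= nc[1] || az >= nc[2] || ax < 0 || ay < 0 || az < 0) continue;
          for (int j : cells[cid(ax, ay, az)]) {
            const double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
            if (dx * dx + dy * dy + dz * dz <= c2) { hit = true; break; }
          }
        }
    out[i] = hit;
  }
  return out;
}

// Normalized spatial discrepancy between two point sets (Kozin-Svergun):
// NSD^2 = 1/2 [ 1/(N1 d2^2) sum_i min_j |a_i-b_j|^2
//             + 1/(N2 d1^2) sum_j min_i |a_i-b_j|^2 ],
// d_k = mean nearest-neighbour spacing within set k.
// [[Rcpp::export]]
double nsd_cpp(NumericMatrix A, NumericMatrix B) {
  const int n1 = A.nrow(), n2 = B.nrow();
  auto min_cross = [](NumericMatrix &P, NumericMatrix &Q) {
    // mean over rows of P of squared distance to nearest row of Q
    const int np = P.nrow(), nq = Q.nrow();
    double acc = 0.0;
    for (int i = 0; i < np; ++i) {
      double best = R_PosInf;
      const double xi = P(i, 0), yi = P(i, 1), zi = P(i, 2);
      for (int j = 0; j < nq; ++j) {
        const double dx = xi - Q(j, 0), dy = yi - Q(j, 1), dz = zi - Q(j, 2);
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
      acc += best;
    }
    return acc / np;
  };
  auto nn_spacing = [](NumericMatrix &P) {
    const int np = P.nrow();
    double acc = 0.0;
    for (int i = 0; i < np; ++i) {
      double best = R_PosInf;
      const double xi = P(i, 0), yi = P(i, 1), zi = P(i, 2);
      for (int j = 0; j < np; ++j) {
        if (j == i) continue;
        const double dx = xi - P(j, 0), dy = yi - P(j, 1), dz = zi - P(j, 2);
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
      acc += std::sqrt(best);
    }
    return acc / np;
  };
  const double d1 = nn_spacing(A), d2 = nn_spacing(B);
  const double t1 = min_cross(A, B) / (d2 * d2);
  const double t2 = min_cross(B, A) / (d1 * d1);
  return std::sqrt(0.5 * (t1 + t2));
}
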