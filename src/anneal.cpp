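// Simulated-annealing bead-phase optimizer for ab initio shape
// reconstruction against a 1D SAXS curve.
//
// Beads sit on a fixed close-packed lattice; the state is the per-bead phase
// label (0 = solvent, 1..P = particle phases with distinct contrasts).  The
// energy is
//   E = chi^2 + w_disc * discontinuity + w_loose * looseness
//            + w_vol * sum_p ((V_p - V_p^exp)/V_p^exp)^2
//            + w_rg  * sum_p ((Rg_p - Rg_p^exp)/Rg_p^exp)^2
// with chi^2 evaluated against the data through a distance-binned Debye sum
// with a free overall scale (optionally plus a constant).  Moves flip the
// phase of one symmetry orbit at a time; the weighted pair-distance
// histogram, phase moments and contact counts are updated incrementally.
// Connectivity (looseness) is refreshed on a lagged schedule because exact
// per-flip dynamic connectivity is prohibitive at ~10^4 beads.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double sphere_ff2(double x) {
  double f;
  if (std::fabs(x) < 1e-5) f = 1.0 - x * x / 10.0;
  else f = 3.0 * (std::sin(x) - x * std::cos(x)) / (x * x * x);
  return f * f;
}
static inline double sincf(double x) {
  if (std::fabs(x) < 1e-8) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

struct Annealer {
  int N, P, ns, nb;
  std::vector<double> x, y, z;
  std::vector<int> phase, allowed;
  std::vector<char> fixed_, memberflag;
  std::vector<double> C;        // contrast per phase 1..P at [p-1]
  double v_cell, bw;
  std::vector<double> s, Iexp, wgt;     // wgt = 1/sigma^2
  std::vector<double> fftab;            // ff^2(s r0) * v_cell^2
  std::vector<double> sinctab;          // nb x ns, row-major by bin
  std::vector<double> W;                // weighted pair histogram
  std::vector<double> raw;              // S1 + sum_b W[b] sinc(s_k d_b)
  double S1;
  std::vector<uint16_t> dmat;
  bool use_dmat;
  std::vector<int> nbr_ptr, nbr_idx, orb_ptr, orb_idx;
  std::vector<int> nphase;              // 0..P
  std::vector<double> Sx, Sy, Sz, Sr2;  // per phase 1..P at [p-1]
  std::vector<int> lk;                  // like-phase contact count
  int lonely, n_nonsolv;
  std::vector<double> vol_t, rg_t;      // targets, <=0 means unused
  double w_vol, w_rg, w_disc, w_loose;
  bool fit_const;
  double loose_cur;
  // scratch
  std::vector<double> dW;
  std::vector<int> touched;
  std::vector<int> bfs_stack, comp_seen;

  inline int bin_of(int i, int j) const {
    if (use_dmat) return dmat[(size_t)i * N + j];
    const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    int b = (int)(std::sqrt(dx * dx + dy * dy + dz * dz) / bw);
    return b >= nb ? nb - 1 : b;
  }
  inline double con(int p) const { return p == 0 ? 0.0 : C[p - 1]; }

  void rebuild_histogram() {
    std::fill(W.begin(), W.end(), 0.0);
    S1 = 0.0;
    for (int i = 0; i < N; ++i) {
      const double ci = con(phase[i]);
      S1 += ci * ci;
      if (ci == 0.0) continue;
      for (int j = i + 1; j < N; ++j) {
        const double cj = con(phase[j]);
        if (cj == 0.0) continue;
        W[bin_of(i, j)] += 2.0 * ci * cj;
      }
    }
    for (int k = 0; k < ns; ++k) {
      double acc = S1;
      for (int b = 0; b < nb; ++b)
        if (W[b] != 0.0) acc += W[b] * sinctab[(size_t)b * ns + k];
      raw[k] = acc;
    }
  }

  void rebuild_bookkeeping() {
    std::fill(nphase.begin(), nphase.end(), 0);
    std::fill(Sx.begin(), Sx.end(), 0.0);
    std::fill(Sy.begin(), Sy.end(), 0.0);
    std::fill(Sz.begin(), Sz.end(), 0.0);
    std::fill(Sr2.begin(), Sr2.end(), 0.0);
    lonely = 0; n_nonsolv = 0;
    for (int i = 0; i < N; ++i) {
      const int p = phase[i];
      nphase[p]++;
      if (p > 0) {
        n_nonsolv++;
        Sx[p - 1] += x[i]; Sy[p - 1] += y[i]; Sz[p - 1] += z[i];
        Sr2[p - 1] += x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
      }
      int c = 0;
      for (int t = nbr_ptr[i]; t < nbr_ptr[i + 1]; ++t)
        if (phase[nbr_idx[t]] == p) c++;
      lk[i] = c;
      if (p > 0 && c < 3) lonely++;
    }
  }

  double looseness() {
    // mean over occupied particle phases of (1 - largestCC/n_phase)
    double acc = 0.0; int used = 0;
    comp_seen.assign(N, 0);
    for (int p = 1; p <= P; ++p) {
      if (nphase[p] == 0) continue;
      used++;
      int maxcc = 0;
      for (int i = 0; i < N; ++i) {
        if (phase[i] != p || comp_seen[i]) continue;
        int sz = 0;
        bfs_stack.clear(); bfs_stack.push_back(i); comp_seen[i] = 1;
        while (!bfs_stack.empty()) {
          int u = bfs_stack.back(); bfs_stack.pop_back(); sz++;
          for (int t = nbr_ptr[u]; t < nbr_ptr[u + 1]; ++t) {
            int v = nbr_idx[t];
            if (phase[v] == p && !comp_seen[v]) { comp_seen[v] = 1; bfs_stack.push_back(v); }
          }
        }
        if (sz > maxcc) maxcc = sz;
      }
      acc += 1.0 - (double)maxcc / nphase[p];
    }
    return used ? acc / used : 0.0;
  }

  void chi2_scale(double &chi2, double &scale, double &cst) const {
    // weighted LS of Iexp on (Im [, 1])
    double swmm = 0, swmy = 0, swm = 0, swy = 0, sw = 0;
    for (int k = 0; k < ns; ++k) {
      const double Im = fftab[k] * raw[k];
      const double w = wgt[k];
      swmm += w * Im * Im; swmy += w * Im * Iexp[k];
      swm += w * Im; swy += w * Iexp[k]; sw += w;
    }
    double c, b0 = 0.0;
    if (fit_const) {
      const double det = swmm * sw - swm * swm;
      if (std::fabs(det) > 1e-300) {
        c = (swmy * sw - swm * swy) / det;
        b0 = (swmm * swy - swm * swmy) / det;
      } else c = swmm > 0 ? swmy / swmm : 0.0;
    } else {
      c = swmm > 0 ? swmy / swmm : 0.0;
    }
    double acc = 0.0;
    for (int k = 0; k < ns; ++k) {
      const double r = Iexp[k] - c * fftab[k] * raw[k] - b0;
      acc += wgt[k] * r * r;
    }
    chi2 = acc / std::max(1, ns - 1);
    scale = c; cst = b0;
  }

  double penalty_vol() const {
    double acc = 0.0;
    for (int p = 1; p <= P; ++p) {
      if (vol_t[p - 1] <= 0) continue;
      const double d = (nphase[p] * v_cell - vol_t[p - 1]) / vol_t[p - 1];
      acc += d * d;
    }
    return acc;
  }
  double penalty_rg() const {
    double acc = 0.0;
    for (int p = 1; p <= P; ++p) {
      if (rg_t[p - 1] <= 0 || nphase[p] < 2) continue;
      const double n = nphase[p];
      const double mx = Sx[p - 1] / n, my = Sy[p - 1] / n, mz = Sz[p - 1] / n;
      double rg2 = Sr2[p - 1] / n - (mx * mx + my * my + mz * mz);
      if (rg2 < 0) rg2 = 0;
      const double d = (std::sqrt(rg2) - rg_t[p - 1]) / rg_t[p - 1];
      acc += d * d;
    }
    return acc;
  }

  double energy(bool exact_loose) {
    double chi2, sc, cst;
    chi2_scale(chi2, sc, cst);
    const double disc = n_nonsolv > 0 ? (double)lonely / n_nonsolv : 0.0;
    double lo = loose_cur;
    if (exact_loose && w_loose > 0) { lo = looseness(); loose_cur = lo; }
    return chi2 + w_disc * disc + w_loose * lo +
           w_vol * penalty_vol() + w_rg * penalty_rg();
  }

  // flip every bead of orbit o (current phase p) to phase q
  void apply_move(int o, int q) {
    const int m0 = orb_idx[orb_ptr[o]];
    const int p = phase[m0];
    const double Cp = con(p), Cq = con(q);
    const double dC = Cq - Cp, dC2 = Cq * Cq - Cp * Cp;
    touched.clear();
    for (int t = orb_ptr[o]; t < orb_ptr[o + 1]; ++t) memberflag[orb_idx[t]] = 1;
    for (int t = orb_ptr[o]; t < orb_ptr[o + 1]; ++t) {
      const int m = orb_idx[t];
      for (int j = 0; j < N; ++j) {
        if (j == m) continue;
        double d;
        if (memberflag[j]) {
          if (j > m) continue;           // each member pair once
          d = 2.0 * dC2;
        } else {
          const double cj = con(phase[j]);
          if (cj == 0.0 && dC == 0.0) continue;
          d = 2.0 * dC * cj;
        }
        if (d == 0.0) continue;
        const int b = bin_of(m, j);
        if (dW[b] == 0.0) touched.push_back(b);
        dW[b] += d;
      }
    }
    // fold deltas into W and raw
    for (int b : touched) {
      const double d = dW[b];
      if (d != 0.0) {
        W[b] += d;
        const double *row = &sinctab[(size_t)b * ns];
        for (int k = 0; k < ns; ++k) raw[k] += d * row[k];
      }
      dW[b] = 0.0;
    }
    // the self term S1 enters raw at every s
    const int nm = orb_ptr[o + 1] - orb_ptr[o];
    S1 += nm * dC2;
    for (int k = 0; k < ns; ++k) raw[k] += nm * dC2;
    // bookkeeping
    for (int t = orb_ptr[o]; t < orb_ptr[o + 1]; ++t) {
      const int m = orb_idx[t];
      if (p > 0) {
        if (lk[m] < 3) lonely--;
        n_nonsolv--;
        Sx[p - 1] -= x[m]; Sy[p - 1] -= y[m]; Sz[p - 1] -= z[m];
        Sr2[p - 1] -= x[m] * x[m] + y[m] * y[m] + z[m] * z[m];
      }
      nphase[p]--;
      // contacts of non-member neighbours
      for (int u = nbr_ptr[m]; u < nbr_ptr[m + 1]; ++u) {
        const int v = nbr_idx[u];
        if (memberflag[v]) continue;     // member-member likeness unchanged
        if (phase[v] == p) {
          if (phase[v] > 0 && lk[v] == 3) lonely++;
          lk[v]--;
        } else if (phase[v] == q) {
          if (phase[v] > 0 && lk[v] == 2) lonely--;
          lk[v]++;
        }
      }
    }
    for (int t = orb_ptr[o]; t < orb_ptr[o + 1]; ++t) phase[orb_idx[t]] = q;
    for (int t = orb_ptr[o]; t < orb_ptr[o + 1]; ++t) {
      const int m = orb_idx[t];
      int c = 0;
      for (int u = nbr_ptr[m]; u < nbr_ptr[m + 1]; ++u)
        if (phase[nbr_idx[u]] == q) c++;
      lk[m] = c;
      nphase[q]++;
      if (q > 0) {
        n_nonsolv++;
        Sx[q - 1] += x[m]; Sy[q - 1] += y[m]; Sz[q - 1] += z[m];
        Sr2[q - 1] += x[m] * x[m] + y[m] * y[m] + z[m] * z[m];
        if (c < 3) lonely++;
      }
    }
    for (int t = orb_ptr[o]; t < orb_ptr[o + 1]; ++t) memberflag[orb_idx[t]] = 0;
  }
};

// [[Rcpp::export]]
List anneal_cpp(NumericMatrix xyz, IntegerVector phase_init,
                IntegerVector allowed, LogicalVector fixed,
                NumericVector contrast, double r0, double v_cell,
                NumericVector s, NumericVector Iexp, NumericVector sigma,
                NumericVector vol_target, NumericVector rg_target,
                double w_vol, double w_rg, double w_disc, double w_loose,
                IntegerVector nbr_ptr, IntegerVector nbr_idx,
                IntegerVector orb_ptr, IntegerVector orb_idx,
                double bin_width, double t0, double cool,
                int sweeps_min, int sweeps_max, int stall_max,
                int loose_every, bool fit_const, bool use_dmat,
                bool exact_loose) {
  Annealer A;
  A.N = xyz.nrow(); A.P = contrast.size(); A.ns = s.size();
  A.x.resize(A.N); A.y.resize(A.N); A.z.resize(A.N);
  for (int i = 0; i < A.N; ++i) {
    A.x[i] = xyz(i, 0); A.y[i] = xyz(i, 1); A.z[i] = xyz(i, 2);
  }
  A.phase = as<std::vector<int>>(phase_init);
  A.allowed = as<std::vector<int>>(allowed);
  A.fixed_.resize(A.N);
  for (int i = 0; i < A.N; ++i) A.fixed_[i] = fixed[i] ? 1 : 0;
  A.memberflag.assign(A.N, 0);
  A.C = as<std::vector<double>>(contrast);
  A.v_cell = v_cell; A.bw = bin_width;
  A.s = as<std::vector<double>>(s);
  A.Iexp = as<std::vector<double>>(Iexp);
  A.wgt.resize(A.ns);
  for (int k = 0; k < A.ns; ++k) A.wgt[k] = 1.0 / (sigma[k] * sigma[k]);
  // max pair distance
  double maxd = 0.0;
  {
    double lo[3] = {A.x[0], A.y[0], A.z[0]}, hi[3] = {A.x[0], A.y[0], A.z[0]};
    for (int i = 0; i < A.N; ++i) {
      lo[0] = std::min(lo[0], A.x[i]); hi[0] = std::max(hi[0], A.x[i]);
      lo[1] = std::min(lo[1], A.y[i]); hi[1] = std::max(hi[1], A.y[i]);
      lo[2] = std::min(lo[2], A.z[i]); hi[2] = std::max(hi[2], A.z[i]);
    }
    for (int a = 0; a < 3; ++a) maxd += (hi[a] - lo[a]) * (hi[a] - lo[a]);
    maxd = std::sqrt(maxd);
  }
  A.nb = (int)(maxd / A.bw) + 2;
  A.use_dmat = use_dmat;
  if (use_dmat) {
    A.dmat.resize((size_t)A.N * A.N);
    for (int i = 0; i < A.N; ++i) {
      for (int j = 0; j < A.N; ++j) {
        const double dx = A.x[i] - A.x[j], dy = A.y[i] - A.y[j], dz = A.z[i] - A.z[j];
        int b = (int)(std::sqrt(dx * dx + dy * dy + dz * dz) / A.bw);
        A.dmat[(size_t)i * A.N + j] = (uint16_t)std::min(b, A.nb - 1);
      }
      if ((i & 255) == 0) Rcpp::checkUserInterrupt();
    }
  }
  A.fftab.resize(A.ns);
  for (int k = 0; k < A.ns; ++k)
    A.fftab[k] = sphere_ff2(A.s[k] * r0) * v_cell * v_cell;
  A.sinctab.resize((size_t)A.nb * A.ns);
  for (int b = 0; b < A.nb; ++b) {
    const double d = (b + 0.5) * A.bw;
    for (int k = 0; k < A.ns; ++k)
      A.sinctab[(size_t)b * A.ns + k] = sincf(A.s[k] * d);
  }
  A.W.assign(A.nb, 0.0);
  A.raw.assign(A.ns, 0.0);
  A.dW.assign(A.nb, 0.0);
  A.nbr_ptr = as<std::vector<int>>(nbr_ptr);
  A.nbr_idx = as<std::vector<int>>(nbr_idx);
  A.orb_ptr = as<std::vector<int>>(orb_ptr);
  A.orb_idx = as<std::vector<int>>(orb_idx);
  A.nphase.assign(A.P + 1, 0);
  A.Sx.assign(A.P, 0.0); A.Sy.assign(A.P, 0.0);
  A.Sz.assign(A.P, 0.0); A.Sr2.assign(A.P, 0.0);
  A.lk.assign(A.N, 0);
  A.vol_t.resize(A.P); A.rg_t.resize(A.P);
  for (int p = 0; p < A.P; ++p) {
    A.vol_t[p] = R_IsNA(vol_target[p]) ? -1.0 : vol_target[p];
    A.rg_t[p] = R_IsNA(rg_target[p]) ? -1.0 : rg_target[p];
  }
  A.w_vol = w_vol; A.w_rg = w_rg; A.w_disc = w_disc; A.w_loose = w_loose;
  A.fit_const = fit_const;

  A.rebuild_histogram();
  A.rebuild_bookkeeping();
  A.loose_cur = (w_loose > 0) ? A.looseness() : 0.0;

  const int norb = (int)A.orb_ptr.size() - 1;
  std::vector<int> movable;
  for (int o = 0; o < norb; ++o) {
    const int m0 = A.orb_idx[A.orb_ptr[o]];
    if (A.fixed_[m0]) continue;
    int opts = 0;
    for (int p = 0; p <= A.P; ++p)
      if (A.allowed[m0] & (1 << p)) opts++;
    if (opts >= 2) movable.push_back(o);
  }

  RNGScope rng;
  auto rand_int = [](int n) { return std::min(n - 1, (int)(unif_rand() * n)); };
  auto pick_target = [&](int o) -> int {
    const int m0 = A.orb_idx[A.orb_ptr[o]];
    const int p = A.phase[m0];
    int opts[8], no = 0;
    for (int q = 0; q <= A.P; ++q)
      if (q != p && (A.allowed[m0] & (1 << q))) opts[no++] = q;
    if (no == 0) return -1;
    return opts[rand_int(no)];
  };

  double E = A.energy(exact_loose && w_loose > 0);
  double T = t0;
  if (t0 < 0) {   // auto-calibrate: ~50% initial acceptance
    std::vector<double> dEs;
    const int ncal = std::min(200, (int)movable.size());
    for (int c = 0; c < ncal; ++c) {
      const int o = movable[rand_int((int)movable.size())];
      const int q = pick_target(o);
      if (q < 0) continue;
      const int m0 = A.orb_idx[A.orb_ptr[o]];
      const int p = A.phase[m0];
      A.apply_move(o, q);
      const double En = A.energy(false);
      dEs.push_back(std::fabs(En - E));
      A.apply_move(o, p);
    }
    if (!dEs.empty()) {
      std::sort(dEs.begin(), dEs.end());
      T = dEs[dEs.size() / 2] / std::log(2.0);
    }
    if (!(T > 0)) T = 1e-3;
    A.rebuild_histogram();   // kill calibration drift
    E = A.energy(exact_loose && w_loose > 0);
  }

  std::vector<int> best_phase = A.phase;
  double bestE = E;
  int stall = 0, sweeps_run = 0;
  long trials = 0, accepted = 0;
  std::vector<double> trace;
  std::vector<int> perm(movable);
  const bool lazy_loose = (w_loose > 0) && !exact_loose && loose_every > 0;
  long acc_since_loose = 0;

  for (int sw = 1; sw <= sweeps_max; ++sw) {
    // Fisher-Yates shuffle via R RNG
    for (int i = (int)perm.size() - 1; i > 0; --i)
      std::swap(perm[i], perm[rand_int(i + 1)]);
    for (int o : perm) {
      const int q = pick_target(o);
      if (q < 0) continue;
      const int m0 = A.orb_idx[A.orb_ptr[o]];
      const int p = A.phase[m0];
      trials++;
      A.apply_move(o, q);
      const double En = A.energy(exact_loose && w_loose > 0);
      const double dE = En - E;
      bool acc = dE <= 0.0;
      if (!acc && T > 0.0) acc = unif_rand() < std::exp(-dE / T);
      if (acc) {
        E = En;
        accepted++;
        if (lazy_loose && ++acc_since_loose >= loose_every) {
          acc_since_loose = 0;
          A.loose_cur = A.looseness();
          E = A.energy(false);
        }
      } else {
        A.apply_move(o, p);
        if (exact_loose && w_loose > 0) { A.loose_cur = A.looseness(); E = A.energy(false); }
      }
    }
    sweeps_run = sw;
    if (sw % 10 == 0) A.rebuild_histogram();   // remove float drift
    if (w_loose > 0) A.loose_cur = A.looseness();
    E = A.energy(false);
    trace.push_back(E);
    if (E < bestE - 1e-12) { bestE = E; best_phase = A.phase; stall = 0; }
    else stall++;
    T *= cool;
    if (sw >= sweeps_min && stall >= stall_max) break;
    Rcpp::checkUserInterrupt();
  }

  // restore best state and report exact final quantities
  A.phase = best_phase;
  A.rebuild_histogram();
  A.rebuild_bookkeeping();
  A.loose_cur = A.looseness();
  double chi2, scale, cst;
  A.chi2_scale(chi2, scale, cst);
  NumericVector Imod(A.ns);
  for (int k = 0; k < A.ns; ++k) Imod[k] = scale * A.fftab[k] * A.raw[k] + cst;
  const double disc = A.n_nonsolv > 0 ? (double)A.lonely / A.n_nonsolv : 0.0;
  const double Efin = chi2 + w_disc * disc + w_loose * A.loose_cur +
                      w_vol * A.penalty_vol() + w_rg * A.penalty_rg();
  IntegerVector ph(A.N);
  for (int i = 0; i < A.N; ++i) ph[i] = A.phase[i];
  return List::create(
      _["phase"] = ph, _["chi2"] = chi2, _["scale"] = scale,
      _["constant"] = cst, _["energy"] = Efin,
      _["discontinuity"] = disc, _["looseness"] = A.loose_cur,
      _["vol_penalty"] = A.penalty_vol(), _["rg_penalty"] = A.penalty_rg(),
      _["I_model"] = Imod, _["sweeps"] = sweeps_run,
      _["trials"] = (double)trials, _["accepted"] = (double)accepted,
      _["energy_trace"] = wrap(trace));
}
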