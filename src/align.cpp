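// Fragment-seeded TM-score alignment core.
//
// Hot loops of the pairwise structural aligner: Kabsch superposition,
// TM-score-optimal transform search (iterative subset refinement), the
// score-matrix + dynamic-programming alignment step, and the full
// fragment-seeded alignment driver. All deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// least-squares proper rotation R, translation t with Q ~ P*R^T + t
// (row-vector convention; R applies to column vectors as q = R p + t)
static double kabsch_core(const arma::mat& P, const arma::mat& Q,
                          arma::mat& R, arma::vec& t) {
  arma::rowvec pc = arma::mean(P, 0), qc = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - pc, Qc = Q.each_row() - qc;
  arma::mat H = Pc.t() * Qc;            // 3x3 covariance
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;       // proper-rotation branch
  R = V * D * U.t();
  t = qc.t() - R * pc.t();
  arma::mat diff = Qc - Pc * R.t();
  if (d < 0) { // recompute with corrected R
    diff = (Q.each_row() - qc) - ((P.each_row() - pc) * R.t());
  }
  double msd = arma::accu(diff % diff) / P.n_rows;
  return std::sqrt(std::max(msd, 0.0));
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& P, const arma::mat& Q) {
  arma::mat R; arma::vec t;
  double rmsd = kabsch_core(P, Q, R, t);
  return List::create(_["rotation"] = R, _["translation"] = t, _["rmsd"] = rmsd);
}

static inline arma::mat apply_rt(const arma::mat& X, const arma::mat& R,
                                 const arma::vec& t) {
  arma::mat Y = X * R.t();
  Y.each_row() += t.t();
  return Y;
}

// TM-score sum over matched pairs for a given transform
static double tm_sum(const arma::mat& Pm, const arma::mat& Ps,
                     const arma::mat& R, const arma::vec& t, double d0) {
  arma::mat Pt = apply_rt(Pm, R, t);
  arma::mat diff = Pt - Ps;
  arma::vec d2 = arma::sum(diff % diff, 1);
  double s = 0, inv = 1.0 / (d0 * d0);
  for (arma::uword i = 0; i < d2.n_elem; ++i) s += 1.0 / (1.0 + d2(i) * inv);
  return s;
}

// TM-score-optimal superposition of matched pairs: seed from windows of
// decreasing length, then iterate superposition on the close-pair subset.
static double refine_tm(const arma::mat& Pm, const arma::mat& Ps, double d0,
                        arma::mat& Rbest, arma::vec& tbest) {
  int n = Pm.n_rows;
  double best = -1.0;
  arma::mat R; arma::vec t;
  if (n < 3) { // degenerate: plain superposition only
    arma::mat P3 = Pm, Q3 = Ps;
    kabsch_core(P3, Q3, Rbest, tbest);
    return tm_sum(Pm, Ps, Rbest, tbest, d0);
  }
  double d_cut0 = std::max(4.5, d0);
  std::vector<int> lens;
  for (int L = n; L >= 4; L /= 2) lens.push_back(L);
  for (size_t li = 0; li < lens.size(); ++li) {
    int L = lens[li];
    int step = std::max(1, L / 2);
    for (int st = 0; st + L <= n; st += step) {
      kabsch_core(Pm.rows(st, st + L - 1), Ps.rows(st, st + L - 1), R, t);
      arma::uvec prev;
      double d_cut = d_cut0;
      for (int it = 0; it < 30; ++it) {
        arma::mat Pt = apply_rt(Pm, R, t);
        arma::vec d2 = arma::sum((Pt - Ps) % (Pt - Ps), 1);
        arma::uvec sel = arma::find(d2 < d_cut * d_cut);
        if ((int)sel.n_elem < 3) { d_cut += 0.5; continue; }
        double s = tm_sum(Pm, Ps, R, t, d0);
        if (s > best) { best = s; Rbest = R; tbest = t; }
        if (prev.n_elem == sel.n_elem && arma::all(prev == sel)) break;
        prev = sel;
        kabsch_core(Pm.rows(sel), Ps.rows(sel), R, t);
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_tm_refine(const arma::mat& Pm, const arma::mat& Ps, double d0) {
  arma::mat R; arma::vec t;
  double s = refine_tm(Pm, Ps, d0, R, t);
  arma::mat diff = apply_rt(Pm, R, t) - Ps;
  double rmsd = std::sqrt(arma::accu(diff % diff) / Pm.n_rows);
  return List::create(_["tm_sum"] = s, _["rotation"] = R,
                      _["translation"] = t, _["rmsd"] = rmsd);
}

// semiglobal DP (free end gaps) maximizing sum of S minus internal gap cost;
// tie-break diagonal > up > left for determinism
static void dp_align(const arma::mat& S, double gap,
                     std::vector<int>& mi, std::vector<int>& mj) {
  int n = S.n_rows, m = S.n_cols;
  arma::mat F(n + 1, m + 1, arma::fill::zeros);
  // pointers: 1 diag, 2 up, 3 left (row-major lookup helper below)
  std::vector<signed char> ptr((n + 1) * (m + 1), 0);
  auto P = [&](int i, int j) -> signed char& { return ptr[i * (m + 1) + j]; };
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = F(i - 1, j - 1) + S(i - 1, j - 1);
      double up = F(i - 1, j) - gap;
      double left = F(i, j - 1) - gap;
      double v = diag; signed char p = 1;
      if (up > v) { v = up; p = 2; }
      if (left > v) { v = left; p = 3; }
      F(i, j) = v; P(i, j) = p;
    }
  }
  // traceback from the best cell on the last row/column (free end gaps)
  int bi = n, bj = m; double bv = F(n, m);
  for (int j = 0; j <= m; ++j) if (F(n, j) > bv) { bv = F(n, j); bi = n; bj = j; }
  for (int i = 0; i <= n; ++i) if (F(i, m) > bv) { bv = F(i, m); bi = i; bj = m; }
  mi.clear(); mj.clear();
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    signed char p = P(i, j);
    if (p == 1) { mi.push_back(i - 1); mj.push_back(j - 1); --i; --j; }
    else if (p == 2) --i;
    else --j;
  }
  std::reverse(mi.begin(), mi.end());
  std::reverse(mj.begin(), mj.end());
}

static void score_matrix(const arma::mat& Xt, const arma::mat& Y, double d0,
                         arma::mat& S) {
  int n = Xt.n_rows, m = Y.n_rows;
  double inv = 1.0 / (d0 * d0);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double dx = Xt(i, 0) - Y(j, 0), dy = Xt(i, 1) - Y(j, 1),
             dz = Xt(i, 2) - Y(j, 2);
      S(i, j) = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) * inv);
    }
  }
}

// one DP round under a transform; returns quick tm_sum after kabsch on the
// resulting mapping
static double seed_round(const arma::mat& X, const arma::mat& Y, double d0,
                         double gap, const arma::mat& R0, const arma::vec& t0,
                         std::vector<int>& mi, std::vector<int>& mj) {
  int n = X.n_rows, m = Y.n_rows;
  arma::mat S(n, m);
  score_matrix(apply_rt(X, R0, t0), Y, d0, S);
  dp_align(S, gap, mi, mj);
  if ((int)mi.size() < 3) return -1.0;
  arma::uvec ui(mi.size()), uj(mj.size());
  for (size_t k = 0; k < mi.size(); ++k) { ui(k) = mi[k]; uj(k) = mj[k]; }
  arma::mat R; arma::vec t;
  kabsch_core(X.rows(ui), Y.rows(uj), R, t);
  return tm_sum(X.rows(ui), Y.rows(uj), R, t, d0);
}

// [[Rcpp::export]]
List cpp_fragment_align(const arma::mat& X, const arma::mat& Y,
                        int F, int S, double gap, int max_iter, double d0,
                        int top_k, const arma::imat& extra_seeds) {
  int n = X.n_rows, m = Y.n_rows;
  if (n < 3 || m < 3) stop("need at least 3 residues in each structure");
  struct Seed { arma::mat R; arma::vec t; double score; std::vector<int> mi, mj; };
  std::vector<Seed> seeds;

  // gapless fragment-pair seeds
  int Fe = std::min(F, std::min(n, m));
  for (int i = 0; i + Fe <= n; i += S) {
    for (int j = 0; j + Fe <= m; j += S) {
      Seed sd;
      kabsch_core(X.rows(i, i + Fe - 1), Y.rows(j, j + Fe - 1), sd.R, sd.t);
      seeds.push_back(std::move(sd));
    }
  }
  // secondary-structure-segment seeds: rows (i, j, len), 0-based
  for (arma::uword r = 0; r < extra_seeds.n_rows; ++r) {
    int i = extra_seeds(r, 0), j = extra_seeds(r, 1), L = extra_seeds(r, 2);
    if (i < 0 || j < 0 || L < 3 || i + L > n || j + L > m) continue;
    Seed sd;
    kabsch_core(X.rows(i, i + L - 1), Y.rows(j, j + L - 1), sd.R, sd.t);
    seeds.push_back(std::move(sd));
  }

  // stage 1: one DP round per seed, keep the top_k by quick score
  for (size_t k = 0; k < seeds.size(); ++k)
    seeds[k].score = seed_round(X, Y, d0, gap, seeds[k].R, seeds[k].t,
                                seeds[k].mi, seeds[k].mj);
  std::vector<int> idx(seeds.size());
  for (size_t k = 0; k < idx.size(); ++k) idx[k] = k;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return seeds[a].score > seeds[b].score; });
  int keep = std::min<int>(top_k, idx.size());

  // stage 2: iterate superpose -> score matrix -> DP until the mapping fixes
  double best_tm = -1.0;
  arma::mat Rb; arma::vec tb; std::vector<int> mib, mjb;
  for (int kk = 0; kk < keep; ++kk) {
    Seed& sd = seeds[idx[kk]];
    if (sd.score < 0) continue;
    std::vector<int> mi = sd.mi, mj = sd.mj;
    arma::mat R; arma::vec t;
    for (int it = 0; it < max_iter; ++it) {
      arma::uvec ui(mi.size()), uj(mj.size());
      for (size_t k = 0; k < mi.size(); ++k) { ui(k) = mi[k]; uj(k) = mj[k]; }
      refine_tm(X.rows(ui), Y.rows(uj), d0, R, t);
      std::vector<int> nmi, nmj;
      arma::mat Smat(n, m);
      score_matrix(apply_rt(X, R, t), Y, d0, Smat);
      dp_align(Smat, gap, nmi, nmj);
      if ((int)nmi.size() < 3) break;
      bool same = (nmi == mi && nmj == mj);
      mi = std::move(nmi); mj = std::move(nmj);
      if (same) break;
    }
    if ((int)mi.size() < 3) continue;
    arma::uvec ui(mi.size()), uj(mj.size());
    for (size_t k = 0; k < mi.size(); ++k) { ui(k) = mi[k]; uj(k) = mj[k]; }
    double s = refine_tm(X.rows(ui), Y.rows(uj), d0, R, t);
    if (s > best_tm) { best_tm = s; Rb = R; tb = t; mib = mi; mjb = mj; }
  }
  if (best_tm < 0) stop("alignment failed: no seed produced >= 3 mapped pairs");
  arma::uvec ui(mib.size()), uj(mjb.size());
  for (size_t k = 0; k < mib.size(); ++k) { ui(k) = mib[k]; uj(k) = mjb[k]; }
  arma::mat diff = apply_rt(X.rows(ui), Rb, tb) - Y.rows(uj);
  double rmsd = std::sqrt(arma::accu(diff % diff) / mib.size());
  IntegerVector mi1(mib.begin(), mib.end()), mj1(mjb.begin(), mjb.end());
  return List::create(_["mi"] = mi1 + 1, _["mj"] = mj1 + 1,
                      _["rotation"] = Rb, _["translation"] = tb,
                      _["tm_sum"] = best_tm, _["rmsd"] = rmsd);
}
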