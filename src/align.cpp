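// Structural alignment core: Kabsch superposition, TM-score optimisation over
// a fixed residue mapping, and a heuristic TM-align-style search (gapless
// diagonal seeds + iterative DP refinement under the current superposition).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Sup {
  arma::mat R;      // 3x3 proper rotation
  arma::vec t;      // translation
  double rmsd;
};

// Least-squares proper rotation mapping points A onto B (rows are points):
// b ~= R * a + t, reflections excluded.
static Sup kabsch(const arma::mat& A, const arma::mat& B) {
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca;
  arma::mat Bc = B.each_row() - cb;
  arma::mat C = Ac.t() * Bc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, C);
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  Sup out;
  out.R = V * D * U.t();
  out.t = cb.t() - out.R * ca.t();
  arma::mat At = Ac * out.R.t();
  out.rmsd = std::sqrt(arma::accu(arma::square(At - Bc)) / A.n_rows);
  return out;
}

static arma::mat transform(const arma::mat& A, const Sup& s) {
  arma::mat At = A * s.R.t();
  At.each_row() += s.t.t();
  return At;
}

static double tm_eval(const arma::mat& At, const arma::mat& B, double d0,
                      double Lnorm) {
  double sum = 0.0;
  const double d02 = d0 * d0;
  for (arma::uword i = 0; i < At.n_rows; ++i) {
    double d2 = arma::accu(arma::square(At.row(i) - B.row(i)));
    sum += 1.0 / (1.0 + d2 / d02);
  }
  return sum / Lnorm;
}

// TM-score over a fixed mapping: maximise over superpositions using seed
// fragments plus iterative inclusion of close pairs (TM-score style search).
static double tm_search(const arma::mat& A, const arma::mat& B, double d0,
                        double Lnorm, Sup& best_sup) {
  const int n = A.n_rows;
  double best = -1.0;
  if (n < 1) return 0.0;
  if (n < 3) {
    // superpose exactly on the available pairs (translation suffices)
    Sup s;
    s.R = arma::eye(3, 3);
    s.t = (arma::mean(B, 0) - arma::mean(A, 0)).t();
    s.rmsd = 0.0;
    best_sup = s;
    return tm_eval(transform(A, s), B, d0, Lnorm);
  }
  std::vector<int> lens;
  for (int l = n; l >= 4; l /= 2) lens.push_back(l);
  if (lens.empty()) lens.push_back(n);
  for (size_t li = 0; li < lens.size(); ++li) {
    const int l = lens[li];
    const int step = std::max(1, l / 2);
    for (int i0 = 0; i0 + l <= n; i0 += step) {
      Sup s = kabsch(A.rows(i0, i0 + l - 1), B.rows(i0, i0 + l - 1));
      // iterative inclusion refinement
      for (int iter = 0; iter < 20; ++iter) {
        arma::mat At = transform(A, s);
        double tm = tm_eval(At, B, d0, Lnorm);
        if (tm > best) { best = tm; best_sup = s; }
        double cut = std::max(d0, 1.0);
        arma::uvec close;
        for (int grow = 0; grow < 10; ++grow) {
          std::vector<arma::uword> idx;
          for (int r = 0; r < n; ++r) {
            double d2 = arma::accu(arma::square(At.row(r) - B.row(r)));
            if (d2 < cut * cut) idx.push_back(r);
          }
          if ((int)idx.size() >= 3) { close = arma::uvec(idx); break; }
          cut += 0.5;
        }
        if (close.n_elem < 3) break;
        Sup s2 = kabsch(A.rows(close), B.rows(close));
        if (arma::norm(s2.t - s.t) < 1e-9 &&
            arma::norm(s2.R - s.R, "fro") < 1e-9) { s = s2; break; }
        s = s2;
      }
      arma::mat At = transform(A, s);
      double tm = tm_eval(At, B, d0, Lnorm);
      if (tm > best) { best = tm; best_sup = s; }
    }
  }
  return best;
}

// Needleman-Wunsch with free end gaps under the current superposition;
// match score 1/(1+(d/d0)^2), linear gap penalty.
static void dp_align(const arma::mat& At, const arma::mat& B, double d0,
                     double gap, std::vector<int>& mi, std::vector<int>& mj) {
  const int la = At.n_rows, lb = B.n_rows;
  const double d02 = d0 * d0;
  arma::mat F(la + 1, lb + 1, arma::fill::zeros);
  arma::Mat<int> ptr(la + 1, lb + 1, arma::fill::zeros);  // 1 diag, 2 up, 3 left
  for (int i = 1; i <= la; ++i) {
    const double ax = At(i - 1, 0), ay = At(i - 1, 1), az = At(i - 1, 2);
    for (int j = 1; j <= lb; ++j) {
      double dx = ax - B(j - 1, 0), dy = ay - B(j - 1, 1), dz = az - B(j - 1, 2);
      double sc = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / d02);
      double diag = F(i - 1, j - 1) + sc;
      double up = F(i - 1, j) + (j == lb ? 0.0 : gap);
      double left = F(i, j - 1) + (i == la ? 0.0 : gap);
      if (diag >= up && diag >= left) { F(i, j) = diag; ptr(i, j) = 1; }
      else if (up >= left)            { F(i, j) = up;   ptr(i, j) = 2; }
      else                            { F(i, j) = left; ptr(i, j) = 3; }
    }
  }
  mi.clear(); mj.clear();
  int i = la, j = lb;
  while (i > 0 && j > 0) {
    if (ptr(i, j) == 1) { mi.push_back(i - 1); mj.push_back(j - 1); --i; --j; }
    else if (ptr(i, j) == 2) --i;
    else --j;
  }
  std::reverse(mi.begin(), mi.end());
  std::reverse(mj.begin(), mj.end());
}

//' @noRd
// [[Rcpp::export(name = ".tm_search_cpp")]]
List tm_search_cpp(NumericMatrix a, NumericMatrix b, double d0, double Lnorm) {
  arma::mat A(a.begin(), a.nrow(), 3, false);
  arma::mat B(b.begin(), b.nrow(), 3, false);
  Sup sup;
  sup.R = arma::eye(3, 3);
  sup.t = arma::zeros(3);
  double tm = tm_search(A, B, d0, Lnorm, sup);
  return List::create(_["tm"] = tm,
                      _["rotation"] = wrap(sup.R),
                      _["translation"] = wrap(sup.t));
}

//' @noRd
// [[Rcpp::export(name = ".kabsch_cpp")]]
List kabsch_cpp(NumericMatrix a, NumericMatrix b) {
  arma::mat A(a.begin(), a.nrow(), 3, false);
  arma::mat B(b.begin(), b.nrow(), 3, false);
  Sup s = kabsch(A, B);
  return List::create(_["rotation"] = wrap(s.R),
                      _["translation"] = wrap(s.t),
                      _["rmsd"] = s.rmsd);
}

//' @noRd
// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(NumericMatrix a, NumericMatrix b, double d0_target,
                    double d0_template, double gap) {
  arma::mat A(a.begin(), a.nrow(), 3, false);
  arma::mat B(b.begin(), b.nrow(), 3, false);
  const int la = A.n_rows, lb = B.n_rows;
  const double d0 = d0_target;

  std::vector<int> best_mi, best_mj;
  double best_tm = -1.0;

  // gapless diagonal seeds: full overlap of each diagonal plus length-8
  // windows stepped along it
  for (int k = -(lb - 1); k <= la - 1; ++k) {
    int i0 = std::max(0, k);
    int j0 = i0 - k;
    int m = std::min(la - i0, lb - j0);
    if (m < 5) continue;
    std::vector<std::pair<int, int> > wins;
    wins.push_back(std::make_pair(0, m));
    if (m >= 16)
      for (int off = 0; off + 8 <= m; off += 8)
        wins.push_back(std::make_pair(off, 8));
    for (size_t w = 0; w < wins.size(); ++w) {
      int s0 = i0 + wins[w].first, t0 = j0 + wins[w].first, wl = wins[w].second;
      Sup s = kabsch(A.rows(s0, s0 + wl - 1), B.rows(t0, t0 + wl - 1));
      std::vector<int> mi, mj;
      for (int iter = 0; iter < 5; ++iter) {
        arma::mat At = transform(A, s);
        dp_align(At, B, d0, gap, mi, mj);
        if ((int)mi.size() < 3) break;
        arma::uvec ui(mi.size()), uj(mj.size());
        for (size_t q = 0; q < mi.size(); ++q) { ui[q] = mi[q]; uj[q] = mj[q]; }
        s = kabsch(A.rows(ui), B.rows(uj));
        double tm = tm_eval(transform(A.rows(ui), s), B.rows(uj), d0, la);
        if (tm > best_tm) { best_tm = tm; best_mi = mi; best_mj = mj; }
      }
    }
  }

  if (best_mi.size() < 3)
    return List::create(_["n"] = 0);

  arma::uvec ui(best_mi.size()), uj(best_mj.size());
  for (size_t q = 0; q < best_mi.size(); ++q) { ui[q] = best_mi[q]; uj[q] = best_mj[q]; }
  arma::mat MA = A.rows(ui), MB = B.rows(uj);
  Sup fin = kabsch(MA, MB);
  Sup st, su;
  double tm_t = tm_search(MA, MB, d0_target, la, st);
  double tm_u = tm_search(MA, MB, d0_template, lb, su);
  IntegerVector rmi(best_mi.begin(), best_mi.end());
  IntegerVector rmj(best_mj.begin(), best_mj.end());
  return List::create(_["n"] = (int)best_mi.size(),
                      _["mi"] = rmi, _["mj"] = rmj,
                      _["rotation"] = wrap(st.R),
                      _["translation"] = wrap(st.t),
                      _["rmsd"] = fin.rmsd,
                      _["tm_target"] = tm_t,
                      _["tm_template"] = tm_u);
}
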