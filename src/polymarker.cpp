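// Weighted linear soft-margin SVM (sequential minimal optimization) and the
// leave-one-out / permutation evaluation core.
//
// The dual problem solved is
//   max_a  sum a_i - 1/2 sum_ij a_i a_j y_i y_j K_ij
//   s.t.   0 <= a_i <= C_i,  sum_i a_i y_i = 0
// with per-sample box constraints C_i (class-imbalance weighting).
//
// The LOO core exploits that the preprocessing chain (standardize ->
// residualize on covariates -> rank-based inverse normal) never sees the
// class labels: per-fold transformed features, Gram matrices and held-out
// kernel vectors are computed once and reused across label permutations,
// which is bit-identical to refitting the preprocessing inside every
// permutation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const double SMO_EPS = 1e-12;

// Sequential minimal optimization with first-order maximal-violating-pair
// working-set selection. Maintains f_t = sum_s a_s y_s K_ts; the KKT
// violation score of sample t is y_t - f_t, maximized over the "up" set
// and minimized over the "down" set.
struct SMOSolver {
  const arma::mat& K;
  const arma::ivec& y;
  const arma::vec& C;
  arma::vec alpha;
  arma::vec f;
  double b;
  double tol;

  SMOSolver(const arma::mat& K_, const arma::ivec& y_, const arma::vec& C_,
            double tol_)
    : K(K_), y(y_), C(C_), alpha(y_.n_elem, arma::fill::zeros),
      f(y_.n_elem, arma::fill::zeros), b(0.0), tol(tol_) {}

  void solve() {
    const int n = y.n_elem;
    const long max_iter = 10000L + 200L * n;
    double m_up = 0, m_lo = 0;
    for (long it = 0; it < max_iter; ++it) {
      int i = -1, j = -1;
      m_up = -arma::datum::inf;
      m_lo = arma::datum::inf;
      for (int t = 0; t < n; ++t) {
        double score = y[t] - f[t];
        bool in_up = (y[t] > 0) ? (alpha[t] < C[t] - SMO_EPS)
                                : (alpha[t] > SMO_EPS);
        bool in_lo = (y[t] > 0) ? (alpha[t] > SMO_EPS)
                                : (alpha[t] < C[t] - SMO_EPS);
        if (in_up && score > m_up) { m_up = score; i = t; }
        if (in_lo && score < m_lo) { m_lo = score; j = t; }
      }
      if (i < 0 || j < 0 || m_up - m_lo < tol) break;
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad < 1e-12) quad = 1e-12;
      double d = (m_up - m_lo) / quad;
      // feasible range for the step keeping both alphas inside their box
      double lo, hi;
      if (y[i] > 0) { lo = -alpha[i]; hi = C[i] - alpha[i]; }
      else          { lo = alpha[i] - C[i]; hi = alpha[i]; }
      double lo_j, hi_j;
      if (y[j] > 0) { lo_j = alpha[j] - C[j]; hi_j = alpha[j]; }
      else          { lo_j = -alpha[j]; hi_j = C[j] - alpha[j]; }
      lo = std::max(lo, lo_j);
      hi = std::min(hi, hi_j);
      if (d > hi) d = hi;
      if (d < lo) d = lo;
      if (std::abs(d) < SMO_EPS) break;
      alpha[i] += y[i] * d;
      alpha[j] -= y[j] * d;
      for (int t = 0; t < n; ++t) f[t] += d * (K(t, i) - K(t, j));
    }
    // offset: average over free support vectors, else midpoint of the
    // violating-pair interval
    arma::uvec freeSV = arma::find(alpha > SMO_EPS && alpha < C - SMO_EPS);
    if (freeSV.n_elem > 0) {
      double acc = 0.0;
      for (arma::uword t = 0; t < freeSV.n_elem; ++t)
        acc += y[freeSV[t]] - f[freeSV[t]];
      b = acc / freeSV.n_elem;
    } else {
      b = 0.5 * (m_up + m_lo);
    }
  }
};

void rin_scores(const arma::vec& v, arma::vec& scores) {
  // Blom-offset inverse-normal scores with average ranks for ties
  const arma::uword n = v.n_elem;
  arma::uvec ord = arma::stable_sort_index(v);
  arma::vec rank(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && v[ord[j + 1]] == v[ord[i]]) ++j;
    double avg = 0.5 * (static_cast<double>(i) + static_cast<double>(j)) + 1.0;
    for (arma::uword t = i; t <= j; ++t) rank[ord[t]] = avg;
    i = j + 1;
  }
  for (arma::uword t = 0; t < n; ++t) {
    scores[t] = R::qnorm((rank[t] - 0.375) / (n + 0.25), 0.0, 1.0, 1, 0);
  }
}

double rin_interp(const arma::vec& xs, const arma::vec& ys, double x0) {
  // linear interpolation over sorted unique (value, score) pairs, clamped
  const arma::uword n = xs.n_elem;
  if (x0 <= xs[0]) return ys[0];
  if (x0 >= xs[n - 1]) return ys[n - 1];
  arma::uword lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    arma::uword mid = (lo + hi) / 2;
    if (xs[mid] <= x0) lo = mid; else hi = mid;
  }
  if (xs[hi] == xs[lo]) return ys[lo];
  double w = (x0 - xs[lo]) / (xs[hi] - xs[lo]);
  return (1.0 - w) * ys[lo] + w * ys[hi];
}

// standardize -> residualize -> (optionally) inverse-normal, fitted on the
// rows `tr` and applied to both `tr` and the single held-out row `ho`.
void preprocess_fold(const arma::mat& X, const arma::mat& Z,
                     const arma::uvec& tr, arma::uword ho, bool rin,
                     arma::mat& Xtr_out, arma::rowvec& xho_out) {
  const arma::uword p = X.n_cols;
  arma::mat Xtr = X.rows(tr);
  arma::rowvec xho = X.row(ho);
  // standardize on the training rows
  arma::rowvec mu = arma::mean(Xtr, 0);
  arma::rowvec sd = arma::stddev(Xtr, 0, 0); // n-1 denominator
  for (arma::uword j = 0; j < p; ++j) {
    if (sd[j] < 1e-12) stop("constant feature column in a training fold");
  }
  Xtr.each_row() -= mu;
  Xtr.each_row() /= sd;
  xho = (xho - mu) / sd;
  // residualize on the covariate design (if any)
  if (Z.n_cols > 0) {
    arma::mat Ztr = Z.rows(tr);
    arma::mat B;
    bool ok = arma::solve(B, Ztr.t() * Ztr, Ztr.t() * Xtr,
                          arma::solve_opts::no_approx);
    if (!ok) B = arma::pinv(Ztr.t() * Ztr) * (Ztr.t() * Xtr);
    Xtr -= Ztr * B;
    xho -= Z.row(ho) * B;
  }
  if (rin) {
    const arma::uword nt = Xtr.n_rows;
    arma::vec scores(nt);
    for (arma::uword j = 0; j < p; ++j) {
      arma::vec v = Xtr.col(j);
      rin_scores(v, scores);
      // unique sorted reference for the held-out interpolation
      arma::uvec ord = arma::stable_sort_index(v);
      arma::vec xs(nt), ys(nt);
      arma::uword m = 0;
      for (arma::uword t = 0; t < nt; ++t) {
        double val = v[ord[t]];
        if (m > 0 && xs[m - 1] == val) continue; // ties share one score
        xs[m] = val;
        ys[m] = scores[ord[t]];
        ++m;
      }
      xho[j] = rin_interp(xs.head(m), ys.head(m), xho[j]);
      Xtr.col(j) = scores;
    }
  }
  Xtr_out = Xtr;
  xho_out = xho;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_svm_train(const arma::mat& X, const arma::ivec& y,
                   const arma::vec& Cvec, double tol = 1e-6) {
  if (X.n_rows != y.n_elem || y.n_elem != Cvec.n_elem)
    stop("dimension mismatch");
  arma::mat K = X * X.t();
  SMOSolver smo(K, y, Cvec, tol);
  smo.solve();
  arma::vec ay = smo.alpha % arma::conv_to<arma::vec>::from(y);
  arma::vec w = X.t() * ay;
  return List::create(_["alpha"] = smo.alpha, _["w"] = w, _["b"] = smo.b);
}

//' @noRd
// [[Rcpp::export]]
List cpp_preprocess_loo(const arma::mat& X, const arma::mat& Z,
                        arma::uword hold, bool rin) {
  // single-fold preprocessing, exposed for cross-checking the R path
  arma::uvec tr(X.n_rows - 1);
  arma::uword m = 0;
  for (arma::uword i = 0; i < X.n_rows; ++i) if (i != hold) tr[m++] = i;
  arma::mat Xtr;
  arma::rowvec xho;
  preprocess_fold(X, Z, tr, hold, rin, Xtr, xho);
  return List::create(_["train"] = Xtr, _["holdout"] = xho);
}

//' @noRd
// [[Rcpp::export]]
arma::mat cpp_loo_decisions(const arma::mat& X, const arma::mat& Z,
                            const arma::imat& labels, double C,
                            bool rin = true, bool paper_mode = false,
                            double tol = 1e-6) {
  const arma::uword n = X.n_rows;
  const arma::uword B = labels.n_cols;
  if (labels.n_rows != n) stop("label matrix must have one row per subject");

  // per-fold cache: Gram of the transformed training rows plus the
  // held-out kernel vector (label-independent, shared across permutations)
  std::vector<arma::mat> Klist(n);
  std::vector<arma::vec> kvec(n);
  std::vector<arma::uvec> trlist(n);

  arma::mat Xfull;
  if (paper_mode) {
    // leaky variant: preprocessing fitted once on the full sample
    arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
    arma::rowvec mu = arma::mean(X, 0);
    arma::rowvec sd = arma::stddev(X, 0, 0);
    for (arma::uword j = 0; j < X.n_cols; ++j)
      if (sd[j] < 1e-12) stop("constant feature column");
    Xfull = X;
    Xfull.each_row() -= mu;
    Xfull.each_row() /= sd;
    if (Z.n_cols > 0) {
      arma::mat B0;
      bool ok = arma::solve(B0, Z.t() * Z, Z.t() * Xfull,
                            arma::solve_opts::no_approx);
      if (!ok) B0 = arma::pinv(Z.t() * Z) * (Z.t() * Xfull);
      Xfull -= Z * B0;
    }
    if (rin) {
      arma::vec scores(n);
      for (arma::uword j = 0; j < Xfull.n_cols; ++j) {
        arma::vec v = Xfull.col(j);
        rin_scores(v, scores);
        Xfull.col(j) = scores;
      }
    }
  }

  for (arma::uword i = 0; i < n; ++i) {
    arma::uvec tr(n - 1);
    arma::uword m = 0;
    for (arma::uword t = 0; t < n; ++t) if (t != i) tr[m++] = t;
    trlist[i] = tr;
    arma::mat Xtr;
    arma::rowvec xho;
    if (paper_mode) {
      Xtr = Xfull.rows(tr);
      xho = Xfull.row(i);
    } else {
      preprocess_fold(X, Z, tr, i, rin, Xtr, xho);
    }
    Klist[i] = Xtr * Xtr.t();
    kvec[i] = Xtr * xho.t();
  }

  arma::mat dec(n, B);
  for (arma::uword b = 0; b < B; ++b) {
    for (arma::uword i = 0; i < n; ++i) {
      const arma::uvec& tr = trlist[i];
      arma::ivec ytr(n - 1);
      arma::uword npos = 0;
      for (arma::uword t = 0; t < n - 1; ++t) {
        ytr[t] = labels(tr[t], b);
        if (ytr[t] > 0) ++npos;
      }
      arma::uword nneg = (n - 1) - npos;
      if (npos == 0 || nneg == 0)
        stop("single-class training set in a leave-one-out fold");
      // inverse-frequency class weights normalized to mean one
      double ip = 1.0 / npos, in_ = 1.0 / nneg;
      double norm = 0.5 * (ip + in_);
      double wp = ip / norm, wn = in_ / norm;
      arma::vec Cv(n - 1);
      for (arma::uword t = 0; t < n - 1; ++t)
        Cv[t] = C * (ytr[t] > 0 ? wp : wn);
      SMOSolver smo(Klist[i], ytr, Cv, tol);
      smo.solve();
      arma::vec ay = smo.alpha % arma::conv_to<arma::vec>::from(ytr);
      dec(i, b) = arma::dot(kvec[i], ay) + smo.b;
    }
  }
  return dec;
}
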