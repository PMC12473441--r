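// C-SVC training on a precomputed RBF Gram matrix.
//
// One-vs-one decomposition with the standard SMO solver (maximal-violating
// pair, second-order working-set selection, libsvm's stopping rule at
// eps = 1e-3). Because the kernel is precomputed, every iteration is pure
// table lookup; each binary subproblem copies its kernel block into a
// dense single-precision tile for cache locality.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct BinaryResult {
  std::vector<int> sv;      // local indices into the pair subset
  std::vector<double> coef; // y_i * alpha_i for the SVs
  double rho;
};

// solve one binary C-SVC subproblem on kernel tile Q (n x n, float)
BinaryResult solve_binary(const fmat& Kt, const std::vector<int>& ysub,
                          double C, double eps, long max_iter) {
  const int n = Kt.n_rows;
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  long it = 0;
  double m_val = 0, M_val = 0;
  while (it++ < max_iter) {
    // working set selection
    int i = -1;
    double m = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const bool in_up = (ysub[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      if (in_up) {
        const double s = -ysub[t] * G[t];
        if (s > m) { m = s; i = t; }
      }
    }
    if (i < 0) break;
    const float* Ki = Kt.colptr(i);
    int j = -1;
    double M = std::numeric_limits<double>::infinity();
    double best_gain = 0;
    for (int t = 0; t < n; ++t) {
      const bool in_low = (ysub[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (in_low) {
        const double s = -ysub[t] * G[t];
        if (s < M) M = s;
        if (s < m - 1e-12) {
          double q = Kt(i, i) + Kt(t, t) - 2.0 * ysub[i] * ysub[t] * Ki[t];
          if (q <= 0) q = 1e-12;
          const double gain = (m - s) * (m - s) / q;
          if (gain > best_gain) { best_gain = gain; j = t; }
        }
      }
    }
    m_val = m; M_val = M;
    if (m - M < eps || j < 0) break;
    // analytic step on (i, j): beta is the change of y_i alpha_i
    double q = Kt(i, i) + Kt(j, j) - 2.0 * ysub[i] * ysub[j] * Ki[j];
    if (q <= 0) q = 1e-12;
    const double sj = -ysub[j] * G[j];
    double beta = (m - sj) / q;
    const double cap_i = (ysub[i] > 0) ? (C - alpha[i]) : alpha[i];
    const double cap_j = (ysub[j] > 0) ? alpha[j] : (C - alpha[j]);
    beta = std::min(beta, std::min(cap_i, cap_j));
    if (beta <= 0) break;
    alpha[i] += ysub[i] * beta;
    alpha[j] -= ysub[j] * beta;
    const float* Kj = Kt.colptr(j);
    for (int t = 0; t < n; ++t) {
      G[t] += ysub[t] * beta * (Ki[t] - Kj[t]);
    }
  }
  BinaryResult res;
  res.rho = -(m_val + M_val) / 2.0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-12) {
      res.sv.push_back(t);
      res.coef.push_back(ysub[t] * alpha[t]);
    }
  }
  return res;
}

}  // namespace

// K: full Gram over the training rows; idx: 0-based rows to train on;
// y: class ids (1..L) aligned with idx; returns the one-vs-one machines.
// [[Rcpp::export]]
Rcpp::List svm_ovo_train_cpp(const arma::mat& K, const arma::ivec& idx,
                             const arma::ivec& y, int n_classes, double C,
                             double eps = 1e-3) {
  std::vector<std::vector<int>> members(n_classes);
  for (uword t = 0; t < idx.n_elem; ++t) {
    members[y(t) - 1].push_back(idx(t));
  }
  Rcpp::List pairs;
  for (int a = 0; a < n_classes; ++a) {
    for (int b = a + 1; b < n_classes; ++b) {
      const auto& A = members[a];
      const auto& B = members[b];
      const int n = A.size() + B.size();
      if (A.empty() || B.empty()) continue;
      std::vector<int> rows(n);
      std::vector<int> ysub(n);
      for (size_t t = 0; t < A.size(); ++t) { rows[t] = A[t]; ysub[t] = 1; }
      for (size_t t = 0; t < B.size(); ++t) {
        rows[A.size() + t] = B[t];
        ysub[A.size() + t] = -1;
      }
      fmat Kt(n, n);
      for (int cjj = 0; cjj < n; ++cjj) {
        const double* col = K.colptr(rows[cjj]);
        float* dst = Kt.colptr(cjj);
        for (int rii = 0; rii < n; ++rii) dst[rii] = (float)col[rows[rii]];
      }
      BinaryResult r = solve_binary(Kt, ysub, C, eps, 10000000L);
      std::vector<int> sv_global(r.sv.size());
      for (size_t t = 0; t < r.sv.size(); ++t) {
        sv_global[t] = rows[r.sv[t]];  // 0-based row in the kernel/features
      }
      pairs.push_back(Rcpp::List::create(
          Rcpp::Named("class_pos") = a + 1, Rcpp::Named("class_neg") = b + 1,
          Rcpp::Named("sv") = sv_global, Rcpp::Named("coef") = r.coef,
          Rcpp::Named("rho") = r.rho));
    }
  }
  return pairs;
}

// Ktest: n_test x n_ref kernel block, where the model's sv indices point
// into the reference columns; majority vote over the pairwise machines,
// ties resolved towards the lower class id.
// [[Rcpp::export]]
arma::ivec svm_ovo_predict_cpp(const Rcpp::List& pairs,
                               const arma::mat& Ktest, int n_classes) {
  const int n_te = Ktest.n_rows;
  imat votes(n_te, n_classes, fill::zeros);
  for (int p = 0; p < pairs.size(); ++p) {
    Rcpp::List pr = pairs[p];
    const int a = Rcpp::as<int>(pr["class_pos"]) - 1;
    const int b = Rcpp::as<int>(pr["class_neg"]) - 1;
    Rcpp::IntegerVector sv = pr["sv"];
    Rcpp::NumericVector coef = pr["coef"];
    const double rho = Rcpp::as<double>(pr["rho"]);
    for (int t = 0; t < n_te; ++t) {
      double f = -rho;
      for (int s = 0; s < sv.size(); ++s) {
        f += coef[s] * Ktest(t, sv[s]);
      }
      votes(t, f > 0 ? a : b) += 1;
    }
  }
  ivec out(n_te);
  for (int t = 0; t < n_te; ++t) {
    int best = 0;
    for (int c2 = 1; c2 < n_classes; ++c2) {
      if (votes(t, c2) > votes(t, best)) best = c2;
    }
    out(t) = best + 1;
  }
  return out;
}
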