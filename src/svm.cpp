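// C-support-vector classification for the searchlight hot loop.
//
// The searchlight evaluates hundreds of thousands of small SVM fits
// (n <= ~100 subjects, <= cube_edge^3 features), so the dual problem is
// solved here with a LIBSVM-style SMO (maximal-violating-pair working-set
// selection, stopping tolerance 1e-3).  All randomness (inner-fold
// shuffling) comes from a splitmix64 counter stream keyed on
// (seed, voxel index, outer fold), so results are independent of
// evaluation order and of R's global RNG.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SMO_EPS = 1e-3;
static const double SMO_TAU = 1e-12;
static const double ALPHA_EPS = 1e-12;

static inline uint64_t splitmix64(uint64_t& state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t stream_seed(uint64_t seed, uint64_t voxel, uint64_t fold) {
  uint64_t s = seed;
  uint64_t a = splitmix64(s);
  s = a ^ (voxel * 0x9E3779B97F4A7C15ULL);
  uint64_t b = splitmix64(s);
  s = b ^ (fold * 0xBF58476D1CE4E5B9ULL);
  return splitmix64(s);
}

// Fisher-Yates shuffle driven by splitmix64; modulo bias is irrelevant here.
static void shuffle_idx(std::vector<int>& v, uint64_t seed) {
  uint64_t state = seed;
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(splitmix64(state) % (uint64_t)(i + 1));
    int tmp = v[i]; v[i] = v[j]; v[j] = tmp;
  }
}

// Stratified fold assignment: within each class (label -1 first, then +1,
// members in ascending index order) shuffle, then deal round-robin.
static std::vector<int> stratified_folds(const std::vector<int>& y, int k, uint64_t seed) {
  int n = (int)y.size();
  std::vector<int> fold(n, 0);
  uint64_t state = seed;
  int cls[2] = {-1, 1};
  for (int c = 0; c < 2; ++c) {
    std::vector<int> members;
    for (int i = 0; i < n; ++i) if (y[i] == cls[c]) members.push_back(i);
    shuffle_idx(members, splitmix64(state));
    for (size_t m = 0; m < members.size(); ++m)
      fold[members[m]] = (int)(m % (size_t)k);
  }
  return fold;
}

struct SvmFit {
  std::vector<double> alpha;  // one per training point
  double b;
  bool majority;              // degenerate single-class training set
  int maj_label;
};

// Solve the C-SVC dual on an m x m kernel submatrix (column-major).
static void smo_solve(const std::vector<double>& K, const std::vector<int>& y,
                      double C, SvmFit& fit) {
  int m = (int)y.size();
  fit.alpha.assign(m, 0.0);
  fit.b = 0.0;
  fit.majority = false;
  fit.maj_label = -1;

  int npos = 0;
  for (int i = 0; i < m; ++i) if (y[i] > 0) ++npos;
  if (npos == 0 || npos == m) {  // single-class: majority-rule predictor
    fit.majority = true;
    fit.maj_label = (npos * 2 >= m) ? 1 : -1;
    return;
  }

  std::vector<double> G(m, -1.0);  // gradient of the dual objective
  int max_iter = 10000 + 200 * m;
  double gmax = 0.0, gmin = 0.0;
  for (int iter = 0; iter < max_iter; ++iter) {
    gmax = -HUGE_VAL; gmin = HUGE_VAL;
    int i = -1, j = -1;
    for (int t = 0; t < m; ++t) {
      double v = -y[t] * G[t];
      bool in_up  = (y[t] > 0) ? (fit.alpha[t] < C - ALPHA_EPS) : (fit.alpha[t] > ALPHA_EPS);
      bool in_low = (y[t] > 0) ? (fit.alpha[t] > ALPHA_EPS)     : (fit.alpha[t] < C - ALPHA_EPS);
      if (in_up && v > gmax) { gmax = v; i = t; }
      if (in_low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < SMO_EPS) break;

    double a = K[(size_t)i * m + i] + K[(size_t)j * m + j] - 2.0 * K[(size_t)j * m + i];
    if (a <= 0) a = SMO_TAU;
    double delta = (gmax - gmin) / a;
    double cap_i = (y[i] > 0) ? (C - fit.alpha[i]) : fit.alpha[i];
    double cap_j = (y[j] > 0) ? fit.alpha[j] : (C - fit.alpha[j]);
    if (delta > cap_i) delta = cap_i;
    if (delta > cap_j) delta = cap_j;

    fit.alpha[i] += (y[i] > 0) ? delta : -delta;
    fit.alpha[j] -= (y[j] > 0) ? delta : -delta;
    const double* Ki = &K[(size_t)i * m];
    const double* Kj = &K[(size_t)j * m];
    for (int t = 0; t < m; ++t)
      G[t] += y[t] * delta * (Ki[t] - Kj[t]);
  }

  // intercept: mean of -y*G over free support vectors, else midpoint bound
  double sum = 0.0; int nfree = 0;
  for (int t = 0; t < m; ++t) {
    if (fit.alpha[t] > ALPHA_EPS && fit.alpha[t] < C - ALPHA_EPS) {
      sum += -y[t] * G[t];
      ++nfree;
    }
  }
  fit.b = nfree > 0 ? sum / nfree : 0.5 * (gmax + gmin);
}

// Materialize kernel values between all rows of X.
// kernel: 0 = linear, 1 = rbf with parameter g.
static void full_kernel(const std::vector<double>& dots, const std::vector<double>& sq,
                        int n, int kernel, double g, std::vector<double>& K) {
  K.resize((size_t)n * n);
  if (kernel == 0) {
    K = dots;
  } else {
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double d2 = sq[i] + sq[j] - 2.0 * dots[(size_t)j * n + i];
        if (d2 < 0) d2 = 0;
        K[(size_t)j * n + i] = std::exp(-g * d2);
      }
  }
}

static void gram_dots(const NumericMatrix& X, std::vector<double>& dots, std::vector<double>& sq) {
  int n = X.nrow(), d = X.ncol();
  dots.assign((size_t)n * n, 0.0);
  for (int c = 0; c < d; ++c) {
    const double* col = &X(0, c);
    for (int j = 0; j < n; ++j) {
      double xj = col[j];
      for (int i = 0; i <= j; ++i) dots[(size_t)j * n + i] += col[i] * xj;
    }
  }
  for (int j = 0; j < n; ++j)
    for (int i = j + 1; i < n; ++i) dots[(size_t)j * n + i] = dots[(size_t)i * n + j];
  sq.resize(n);
  for (int i = 0; i < n; ++i) sq[i] = dots[(size_t)i * n + i];
}

// Extract training submatrix of K for indices idx.
static void sub_kernel(const std::vector<double>& K, int n, const std::vector<int>& idx,
                       std::vector<double>& Ksub) {
  int m = (int)idx.size();
  Ksub.resize((size_t)m * m);
  for (int j = 0; j < m; ++j) {
    const double* col = &K[(size_t)idx[j] * n];
    double* out = &Ksub[(size_t)j * m];
    for (int i = 0; i < m; ++i) out[i] = col[idx[i]];
  }
}

static int predict_one(const SvmFit& fit, const std::vector<double>& K, int n,
                       const std::vector<int>& train_idx, const std::vector<int>& ytr,
                       int test) {
  if (fit.majority) return fit.maj_label;
  double dec = fit.b;
  const double* col = &K[(size_t)test * n];  // symmetric: K[test, i]
  for (size_t a = 0; a < train_idx.size(); ++a)
    if (fit.alpha[a] > ALPHA_EPS)
      dec += fit.alpha[a] * ytr[a] * col[train_idx[a]];
  return dec >= 0 ? 1 : -1;
}

// Inner CV accuracy (number correct) for one (C, kernel) on training set idx.
static int inner_cv_correct(const std::vector<double>& K, int n,
                            const std::vector<int>& idx, const std::vector<int>& y,
                            const std::vector<int>& fold, int k, double C,
                            std::vector<double>& Ksub_buf) {
  int correct = 0;
  for (int f = 0; f < k; ++f) {
    std::vector<int> tr, te;
    std::vector<int> ytr;
    for (size_t a = 0; a < idx.size(); ++a) {
      if (fold[a] == f) te.push_back((int)a);
      else { tr.push_back(idx[a]); ytr.push_back(y[idx[a]]); }
    }
    if (te.empty()) continue;
    SvmFit fit;
    if (tr.empty()) { fit.majority = true; fit.maj_label = -1; }
    else {
      sub_kernel(K, n, tr, Ksub_buf);
      smo_solve(Ksub_buf, ytr, C, fit);
    }
    for (size_t a = 0; a < te.size(); ++a) {
      int gi = idx[te[a]];
      int pred = predict_one(fit, K, n, tr, ytr, gi);
      if (pred == y[gi]) ++correct;
    }
  }
  return correct;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_inner_folds")]]
IntegerVector cpp_inner_folds(IntegerVector y, int k, double seed, double voxel_index,
                              double outer_index) {
  std::vector<int> yv(y.begin(), y.end());
  uint64_t s = stream_seed((uint64_t)seed, (uint64_t)voxel_index, (uint64_t)outer_index);
  std::vector<int> fold = stratified_folds(yv, k, s);
  return IntegerVector(fold.begin(), fold.end());
}

//' @noRd
// [[Rcpp::export(name = ".cpp_svm_train")]]
List cpp_svm_train(NumericMatrix K, IntegerVector y, double C) {
  int m = y.size();
  std::vector<double> Kv(K.begin(), K.end());
  std::vector<int> yv(y.begin(), y.end());
  SvmFit fit;
  smo_solve(Kv, yv, C, fit);
  return List::create(_["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["b"] = fit.b,
                      _["majority"] = fit.majority,
                      _["majority_label"] = fit.maj_label,
                      _["n"] = m);
}

// Leave-one-out accuracy with nested grid search at one voxel.
// kernel: 0 linear (g_grid ignored), 1 rbf.
//' @noRd
// [[Rcpp::export(name = ".cpp_loo_accuracy")]]
List cpp_loo_accuracy(NumericMatrix X, IntegerVector y, int kernel,
                      NumericVector c_grid, NumericVector g_grid,
                      int inner_folds, double seed, double voxel_index,
                      bool details) {
  int n = X.nrow();
  std::vector<int> yv(y.begin(), y.end());

  std::vector<double> dots, sq;
  gram_dots(X, dots, sq);
  int ng = (kernel == 0) ? 1 : g_grid.size();
  std::vector<std::vector<double> > Kg(ng);
  for (int gi = 0; gi < ng; ++gi)
    full_kernel(dots, sq, n, kernel, kernel == 0 ? 0.0 : g_grid[gi], Kg[gi]);

  bool do_search = ((int)c_grid.size() * ng) > 1;
  std::vector<double> Ksub;
  int correct = 0;
  NumericVector det_C(details ? n : 0), det_g(details ? n : 0);
  IntegerVector det_train(details ? n : 0), det_feat(details ? n : 0);

  for (int t = 0; t < n; ++t) {
    std::vector<int> train;
    train.reserve(n - 1);
    for (int i = 0; i < n; ++i) if (i != t) train.push_back(i);
    std::vector<int> ytr;
    for (size_t a = 0; a < train.size(); ++a) ytr.push_back(yv[train[a]]);

    int best_c = 0, best_g = 0;
    if (do_search) {
      std::vector<int> fold_raw;
      {
        IntegerVector f = cpp_inner_folds(IntegerVector(ytr.begin(), ytr.end()),
                                          inner_folds, seed, voxel_index, (double)(t + 1));
        fold_raw.assign(f.begin(), f.end());
      }
      int best_correct = -1;
      for (int ci = 0; ci < c_grid.size(); ++ci) {
        for (int gi = 0; gi < ng; ++gi) {
          int corr = inner_cv_correct(Kg[gi], n, train, yv, fold_raw, inner_folds,
                                      c_grid[ci], Ksub);
          if (corr > best_correct) { best_correct = corr; best_c = ci; best_g = gi; }
        }
      }
    }

    const std::vector<double>& K = Kg[best_g];
    sub_kernel(K, n, train, Ksub);
    SvmFit fit;
    smo_solve(Ksub, ytr, c_grid[best_c], fit);
    int pred = predict_one(fit, K, n, train, ytr, t);
    if (pred == yv[t]) ++correct;
    if (details) {
      det_C[t] = c_grid[best_c];
      det_g[t] = kernel == 0 ? NA_REAL : g_grid[best_g];
      det_train[t] = (int)train.size();
      det_feat[t] = X.ncol();
    }
  }

  List out = List::create(_["accuracy"] = (double)correct / n,
                          _["n_correct"] = correct,
                          _["n"] = n);
  if (details)
    out["folds"] = DataFrame::create(_["fold"] = seq_len(n),
                                     _["train_size"] = det_train,
                                     _["n_features"] = det_feat,
                                     _["C"] = det_C,
                                     _["gamma"] = det_g);
  return out;
}
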