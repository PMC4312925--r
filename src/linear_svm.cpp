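#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// L2-regularized L1-loss (hinge) linear SVM, solved in the dual by
// coordinate descent (Hsieh et al. 2008, the LIBLINEAR L2R_L1LOSS_SVC_DUAL
// solver). The bias is handled by augmenting each example with a constant
// feature of value 1, so it is regularized along with the weights.
//
//   min_w  0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w'x_i)
//
// X: n x p feature matrix (row = example), y: +1/-1 labels.
// Returns the (p+1)-vector (w, b).
//
// The sweep order is shuffled with a fixed-seed generator so results are
// bit-reproducible across calls and platforms. Examples are copied into a
// row-contiguous buffer so the inner dot products stream through memory.

static void cd_solve(const std::vector<double> &Xr, const double *y,
                     int n, int p, double C, double eps, int max_iter,
                     std::vector<double> &w) {
  const int pb = p + 1;
  w.assign(pb, 0.0);
  std::vector<double> alpha(n, 0.0), qd(n);
  for (int i = 0; i < n; ++i) {
    const double *xi = &Xr[static_cast<size_t>(i) * p];
    double s = 1.0;  // augmented bias feature
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    qd[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::mt19937 rng(88172645u);

  for (int iter = 0; iter < max_iter; ++iter) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double max_pg = 0.0;
    for (int k = 0; k < n; ++k) {
      const int i = idx[k];
      const double yi = y[i];
      const double *xi = &Xr[static_cast<size_t>(i) * p];
      double wx = w[p];  // bias feature contribution
      for (int j = 0; j < p; ++j) wx += w[j] * xi[j];
      const double g = yi * wx - 1.0;
      // projected gradient on the box [0, C]
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      else if (alpha[i] >= C && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (pg != 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - g / qd[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double d = (a_new - a_old) * yi;
        for (int j = 0; j < p; ++j) w[j] += d * xi[j];
        w[p] += d;
      }
    }
    if (max_pg < eps) break;
  }
}

// [[Rcpp::export]]
NumericVector svm_linear_cd(NumericMatrix X, NumericVector y, double C,
                            double eps = 0.1, int max_iter = 1000) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> Xr(static_cast<size_t>(n) * p);
  for (int j = 0; j < p; ++j) {
    const double *col = &X(0, j);
    for (int i = 0; i < n; ++i) Xr[static_cast<size_t>(i) * p + j] = col[i];
  }
  std::vector<double> w;
  cd_solve(Xr, REAL(y), n, p, C, eps, max_iter, w);
  NumericVector out(p + 1);
  for (int j = 0; j <= p; ++j) out[j] = w[j];
  return out;
}

// One permuted (or observed) run of the fixed-C per-subject pipeline:
// optional label shuffle, class balancing by down-sampling, stratified
// train/test split, per-feature standardization on training rows, hinge
// SVM fit at C, held-out accuracy. All randomness comes from a seeded
// generator so every (subject, permutation) pair is reproducible.
//
// X: n x p (rows = trials of correct responses, features = voxels),
// y: +1/-1. Returns the test-set accuracy.

// [[Rcpp::export]]
double pipeline_accuracy_cpp(NumericMatrix X, NumericVector y, double C,
                             double train_fraction, int seed,
                             bool standardize = true,
                             bool shuffle_labels = false,
                             double eps = 0.1, int max_iter = 1000) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<double> yy(REAL(y), REAL(y) + n);
  if (shuffle_labels) std::shuffle(yy.begin(), yy.end(), rng);

  std::vector<int> pos, neg;
  for (int i = 0; i < n; ++i) (yy[i] > 0 ? pos : neg).push_back(i);
  if (pos.empty() || neg.empty()) Rcpp::stop("both classes must be non-empty");
  const int nb = static_cast<int>(std::min(pos.size(), neg.size()));
  std::shuffle(pos.begin(), pos.end(), rng);
  std::shuffle(neg.begin(), neg.end(), rng);
  pos.resize(nb); neg.resize(nb);

  const int ntr_c = static_cast<int>(std::lround(train_fraction * nb));
  if (ntr_c < 1 || ntr_c >= nb)
    Rcpp::stop("train fraction leaves an empty train or test partition");
  std::shuffle(pos.begin(), pos.end(), rng);
  std::shuffle(neg.begin(), neg.end(), rng);

  std::vector<int> train, test;
  train.insert(train.end(), pos.begin(), pos.begin() + ntr_c);
  train.insert(train.end(), neg.begin(), neg.begin() + ntr_c);
  test.insert(test.end(), pos.begin() + ntr_c, pos.end());
  test.insert(test.end(), neg.begin() + ntr_c, neg.end());
  const int ntr = static_cast<int>(train.size());
  const int nte = static_cast<int>(test.size());

  // per-feature standardization from training rows
  std::vector<double> ctr(p, 0.0), scl(p, 1.0);
  if (standardize) {
    for (int j = 0; j < p; ++j) {
      const double *col = &X(0, j);
      double s = 0.0, s2 = 0.0;
      for (int k = 0; k < ntr; ++k) { const double v = col[train[k]]; s += v; s2 += v * v; }
      const double m = s / ntr;
      double var = (s2 / ntr - m * m) * ntr / std::max(ntr - 1, 1);
      if (var < 0) var = 0;
      double sd = std::sqrt(var);
      ctr[j] = m;
      scl[j] = (sd < 1e-12) ? 1.0 : sd;
    }
  }

  std::vector<double> Xtr(static_cast<size_t>(ntr) * p), ytr(ntr);
  for (int k = 0; k < ntr; ++k) {
    const int i = train[k];
    ytr[k] = yy[i];
    for (int j = 0; j < p; ++j)
      Xtr[static_cast<size_t>(k) * p + j] = (X(i, j) - ctr[j]) / scl[j];
  }
  std::vector<double> w;
  cd_solve(Xtr, ytr.data(), ntr, p, C, eps, max_iter, w);

  int correct = 0;
  for (int k = 0; k < nte; ++k) {
    const int i = test[k];
    double s = w[p];
    for (int j = 0; j < p; ++j) s += w[j] * (X(i, j) - ctr[j]) / scl[j];
    const double pred = (s > 0) ? 1.0 : -1.0;
    if (pred == yy[i]) ++correct;
  }
  return static_cast<double>(correct) / nte;
}
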