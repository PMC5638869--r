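// Built-in classifiers and the k-fold confusion-count driver.
//
// Everything here is deliberately deterministic: no RNG, ties broken by
// index, so that repeated evaluations of the same subset are bit-identical.
// Matrices are samples x features and small (tens to a few hundred samples,
// at most a few hundred features), so dense direct solvers are appropriate.

#include <RcppArmadillo.h>
#include <algorithm>
#include <cmath>
#include <string>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;
using arma::uvec;
using arma::ivec;

static const double LSSVM_COST = 1.0;   // C in (K + I/C)
static const double LOGREG_L2 = 1.0;    // ridge penalty on non-intercept weights
static const int KNN_K = 5;
static const int TREE_MAX_DEPTH = 30;

// ---------------------------------------------------------------------------
// helpers

// squared Euclidean distances between rows of A and rows of B
static mat pairwise_sqdist(const mat& A, const mat& B) {
  mat D = -2.0 * A * B.t();
  vec a2 = arma::sum(arma::square(A), 1);
  vec b2 = arma::sum(arma::square(B), 1);
  D.each_col() += a2;
  D.each_row() += b2.t();
  D.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return D;
}

static int majority_class(const ivec& y) {
  int pos = (int) arma::sum(y);
  int neg = (int) y.n_elem - pos;
  return pos > neg ? 1 : 0;  // tie -> negative
}

// ---------------------------------------------------------------------------
// Gaussian naive Bayes (per-class feature means/variances, shared smoothing)

static ivec predict_nbayes(const mat& Xtr, const ivec& ytr, const mat& Xte) {
  const arma::uword d = Xtr.n_cols;
  uvec idx1 = arma::find(ytr == 1), idx0 = arma::find(ytr == 0);
  double n = (double) Xtr.n_rows;

  // variance smoothing proportional to the largest overall feature variance
  vec vall = arma::var(Xtr, 1, 0).t();  // ML variance per feature
  double eps = 1e-9 * (vall.n_elem ? vall.max() : 1.0);
  if (eps <= 0.0) eps = 1e-9;

  mat mu(2, d), va(2, d);
  double lp0 = std::log(idx0.n_elem / n), lp1 = std::log(idx1.n_elem / n);
  mu.row(0) = arma::mean(Xtr.rows(idx0), 0);
  mu.row(1) = arma::mean(Xtr.rows(idx1), 0);
  va.row(0) = (idx0.n_elem > 1 ? arma::var(Xtr.rows(idx0), 1, 0)
                               : arma::rowvec(d, arma::fill::zeros)) + eps;
  va.row(1) = (idx1.n_elem > 1 ? arma::var(Xtr.rows(idx1), 1, 0)
                               : arma::rowvec(d, arma::fill::zeros)) + eps;

  ivec out(Xte.n_rows);
  for (arma::uword i = 0; i < Xte.n_rows; ++i) {
    double l0 = lp0, l1 = lp1;
    for (arma::uword j = 0; j < d; ++j) {
      double x = Xte(i, j);
      l0 += -0.5 * (std::log(2.0 * M_PI * va(0, j)) +
                    (x - mu(0, j)) * (x - mu(0, j)) / va(0, j));
      l1 += -0.5 * (std::log(2.0 * M_PI * va(1, j)) +
                    (x - mu(1, j)) * (x - mu(1, j)) / va(1, j));
    }
    out(i) = l1 > l0 ? 1 : 0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// k nearest neighbours (k = 5, Euclidean, distance then index tie-break)

// D: test x train squared distances (precomputed once per subset)
static ivec knn_from_dist(const mat& D, const ivec& ytr) {
  int ntr = (int) D.n_cols;
  int k = std::min(KNN_K, ntr);
  ivec out(D.n_rows);
  std::vector<std::pair<double, int>> ord(ntr);
  for (arma::uword i = 0; i < D.n_rows; ++i) {
    for (int j = 0; j < ntr; ++j) ord[j] = std::make_pair(D(i, j), j);
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end());
    int votes = 0;
    for (int j = 0; j < k; ++j) votes += (int) ytr(ord[j].second);
    if (2 * votes > k) out(i) = 1;
    else if (2 * votes < k) out(i) = 0;
    else out(i) = (int) ytr(ord[0].second);  // even-k tie: nearest neighbour
  }
  return out;
}

static ivec predict_knn(const mat& Xtr, const ivec& ytr, const mat& Xte) {
  return knn_from_dist(pairwise_sqdist(Xte, Xtr), ytr);
}

// ---------------------------------------------------------------------------
// CART decision tree, Gini impurity, grown to purity (depth-capped)

struct TreeNode {
  int feat;      // -1 for leaf
  double thr;
  int left, right;
  int pred;
};

// Each node holds, per feature, the node's sample indices sorted by that
// feature's value (pre-sorted once, then stably partitioned down the
// recursion -- no per-node sorting).
static int tree_grow(std::vector<TreeNode>& nodes, const mat& X, const ivec& y,
                     std::vector<std::vector<int>>& order, int depth) {
  int d = (int) order.size();
  int n = (int) order[0].size();
  int pos = 0;
  for (int i = 0; i < n; ++i) pos += (int) y(order[0][(size_t) i]);
  int neg = n - pos;

  TreeNode node;
  node.feat = -1;
  node.thr = 0.0;
  node.left = node.right = -1;
  node.pred = pos > neg ? 1 : 0;

  if (pos == 0 || neg == 0 || n < 2 || depth >= TREE_MAX_DEPTH) {
    nodes.push_back(node);
    return (int) nodes.size() - 1;
  }

  double p1 = (double) pos / n, p0 = (double) neg / n;
  double gini_parent = 1.0 - p1 * p1 - p0 * p0;
  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  for (int j = 0; j < d; ++j) {
    const double* col = X.colptr((arma::uword) j);
    const std::vector<int>& ord = order[(size_t) j];
    int lpos = 0;
    for (int i = 0; i < n - 1; ++i) {
      lpos += (int) y(ord[(size_t) i]);
      double vi = col[ord[(size_t) i]], vn = col[ord[(size_t) i + 1]];
      if (vn <= vi) continue;  // no split between equal values
      int ln = i + 1, rn = n - ln;
      int rpos = pos - lpos;
      double lp = (double) lpos / ln, rp = (double) rpos / rn;
      double gl = 1.0 - lp * lp - (1.0 - lp) * (1.0 - lp);
      double gr = 1.0 - rp * rp - (1.0 - rp) * (1.0 - rp);
      double gain = gini_parent - ((double) ln / n) * gl - ((double) rn / n) * gr;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (vi + vn);
      }
    }
  }

  if (best_feat < 0) {  // all features constant within the node
    nodes.push_back(node);
    return (int) nodes.size() - 1;
  }

  const double* bcol = X.colptr((arma::uword) best_feat);
  std::vector<std::vector<int>> lorder(d), rorder(d);
  for (int j = 0; j < d; ++j) {
    lorder[(size_t) j].reserve((size_t) n);
    rorder[(size_t) j].reserve((size_t) n);
    for (int s : order[(size_t) j]) {
      if (bcol[s] <= best_thr) lorder[(size_t) j].push_back(s);
      else rorder[(size_t) j].push_back(s);
    }
  }

  node.feat = best_feat;
  node.thr = best_thr;
  nodes.push_back(node);
  int self = (int) nodes.size() - 1;
  int left = tree_grow(nodes, X, y, lorder, depth + 1);
  int right = tree_grow(nodes, X, y, rorder, depth + 1);
  nodes[self].left = left;
  nodes[self].right = right;
  return self;
}

// sorted (by value, then index) sample lists per feature, restricted to
// `keep` (empty = all samples)
static std::vector<std::vector<int>> feature_orders(const mat& X,
                                                    const std::vector<char>& keep) {
  int n = (int) X.n_rows, d = (int) X.n_cols;
  std::vector<std::vector<int>> order((size_t) d);
  std::vector<int> base;
  base.reserve((size_t) n);
  for (int i = 0; i < n; ++i)
    if (keep.empty() || keep[(size_t) i]) base.push_back(i);
  for (int j = 0; j < d; ++j) {
    const double* col = X.colptr((arma::uword) j);
    order[(size_t) j] = base;
    std::stable_sort(order[(size_t) j].begin(), order[(size_t) j].end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }
  return order;
}

static ivec dtree_predict_nodes(const std::vector<TreeNode>& nodes, int root,
                                const mat& Xte) {
  ivec out(Xte.n_rows);
  for (arma::uword i = 0; i < Xte.n_rows; ++i) {
    int cur = root;
    while (nodes[cur].feat >= 0) {
      cur = Xte(i, (arma::uword) nodes[cur].feat) <= nodes[cur].thr
              ? nodes[cur].left : nodes[cur].right;
    }
    out(i) = nodes[cur].pred;
  }
  return out;
}

static ivec predict_dtree(const mat& Xtr, const ivec& ytr, const mat& Xte) {
  std::vector<TreeNode> nodes;
  std::vector<std::vector<int>> order =
      feature_orders(Xtr, std::vector<char>());
  int root = tree_grow(nodes, Xtr, ytr, order, 0);
  return dtree_predict_nodes(nodes, root, Xte);
}

// ---------------------------------------------------------------------------
// least-squares SVM with RBF kernel (gamma = 1 / (d * var(X)), C = 1)

// Dtr: train x train squared distances, Dte: test x train.  The bordered
// KKT system is solved via two SPD solves on K + I/C:
//   A h1 = 1, A ht = t;  b = (1' ht) / (1' h1);  alpha = ht - b h1.
static ivec svm_from_dist(const mat& Dtr, const mat& Dte, const ivec& ytr,
                          double gamma) {
  arma::uword ntr = Dtr.n_rows;
  mat A = arma::exp(-gamma * Dtr);
  A.diag() += 1.0 / LSSVM_COST + 1e-10;

  vec ones(ntr, arma::fill::ones);
  vec t(ntr);
  for (arma::uword i = 0; i < ntr; ++i) t(i) = ytr(i) == 1 ? 1.0 : -1.0;

  mat sol;
  mat rhs = arma::join_rows(ones, t);
  bool ok = arma::solve(sol, A, rhs,
                        arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
  if (!ok) {
    ivec out(Dte.n_rows);
    out.fill(majority_class(ytr));
    return out;
  }
  double denom = arma::dot(ones, sol.col(0));
  double b = denom != 0.0 ? arma::dot(ones, sol.col(1)) / denom : 0.0;
  vec alpha = sol.col(1) - b * sol.col(0);

  vec f = arma::exp(-gamma * Dte) * alpha + b;
  ivec out(Dte.n_rows);
  for (arma::uword i = 0; i < Dte.n_rows; ++i) out(i) = f(i) > 0.0 ? 1 : 0;
  return out;
}

static double rbf_gamma(const mat& Xtr) {
  double vall = arma::var(arma::vectorise(Xtr), 1);
  return (vall > 0.0) ? 1.0 / (Xtr.n_cols * vall) : 1.0 / Xtr.n_cols;
}

static ivec predict_svm(const mat& Xtr, const ivec& ytr, const mat& Xte) {
  return svm_from_dist(pairwise_sqdist(Xtr, Xtr), pairwise_sqdist(Xte, Xtr),
                       ytr, rbf_gamma(Xtr));
}

// ---------------------------------------------------------------------------
// logistic regression, IRLS with a small L2 ridge (keeps separable data finite)

// The Newton step solves (Lambda + Z'WZ) delta = g via the Woodbury
// identity, so the per-iteration factorisation is m x m (sample count)
// rather than (d+1) x (d+1), and the Z Lambda^-1 Z' Gram matrix is built
// once per fit.  The intercept carries a vanishing penalty (1e-4) so that
// Lambda stays invertible.
static ivec predict_logreg(const mat& Xtr, const ivec& ytr, const mat& Xte) {
  arma::uword ntr = Xtr.n_rows, d = Xtr.n_cols;
  mat Z(ntr, d + 1);
  Z.col(0).ones();
  Z.cols(1, d) = Xtr;
  vec y(ntr);
  for (arma::uword i = 0; i < ntr; ++i) y(i) = (double) ytr(i);

  vec lambda(d + 1);
  lambda(0) = 1e-4;
  lambda.subvec(1, d).fill(LOGREG_L2);

  // dual (Woodbury) path only pays off past d + 1 > n_train
  bool dual = d + 1 > ntr;
  vec linv;
  mat G;
  if (dual) {
    linv = 1.0 / lambda;
    G = (Z.each_row() % linv.t()) * Z.t();  // Z Lambda^-1 Z'
  }

  vec w(d + 1, arma::fill::zeros);
  for (int it = 0; it < 25; ++it) {
    vec eta = Z * w;
    vec p = 1.0 / (1.0 + arma::exp(-eta));
    p.transform([](double v) {
      return v < 1e-10 ? 1e-10 : (v > 1.0 - 1e-10 ? 1.0 - 1e-10 : v);
    });
    vec wt = p % (1.0 - p);
    wt.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });

    vec g = Z.t() * (y - p) - lambda % w;
    vec delta;
    bool ok;
    if (dual) {
      vec a = linv % g;
      mat M = G;
      M.diag() += 1.0 / wt;
      vec s;
      ok = arma::solve(s, M, Z * a,
                       arma::solve_opts::likely_sympd +
                       arma::solve_opts::no_approx);
      if (ok) delta = a - linv % (Z.t() * s);
    } else {
      mat H = Z.t() * (Z.each_col() % wt);
      H.diag() += lambda;
      ok = arma::solve(delta, H, g,
                       arma::solve_opts::likely_sympd +
                       arma::solve_opts::no_approx);
    }
    if (!ok) break;
    w += delta;
    if (arma::abs(delta).max() < 1e-5) break;
  }

  mat Zt(Xte.n_rows, d + 1);
  Zt.col(0).ones();
  Zt.cols(1, d) = Xte;
  vec eta = Zt * w;
  ivec out(Xte.n_rows);
  for (arma::uword i = 0; i < Xte.n_rows; ++i) out(i) = eta(i) > 0.0 ? 1 : 0;
  return out;
}

// ---------------------------------------------------------------------------
// dispatch

static ivec predict_by_name(const std::string& name, const mat& Xtr,
                            const ivec& ytr, const mat& Xte) {
  if (name == "SVM") return predict_svm(Xtr, ytr, Xte);
  if (name == "KNN") return predict_knn(Xtr, ytr, Xte);
  if (name == "DTree") return predict_dtree(Xtr, ytr, Xte);
  if (name == "NBayes") return predict_nbayes(Xtr, ytr, Xte);
  if (name == "LR") return predict_logreg(Xtr, ytr, Xte);
  Rcpp::stop("unknown built-in classifier: " + name);
}

// train-fold z-scaling fitted on the training rows only
static void scale_train_test(mat& Xtr, mat& Xte) {
  arma::rowvec mu = arma::mean(Xtr, 0);
  arma::rowvec sd = arma::stddev(Xtr, 0, 0);
  sd.transform([](double v) { return v > 0.0 ? v : 1.0; });
  Xtr.each_row() -= mu;
  Xtr.each_row() /= sd;
  Xte.each_row() -= mu;
  Xte.each_row() /= sd;
}

// [[Rcpp::export(name = ".cv_counts_cpp")]]
Rcpp::IntegerMatrix cv_counts_cpp(const arma::mat& X, const arma::ivec& y,
                                  const arma::ivec& fold, int nfold,
                                  const std::vector<std::string>& classifiers,
                                  bool scale) {
  int nclf = (int) classifiers.size();
  Rcpp::IntegerMatrix counts(nclf, 4);  // TP FN FP TN, pooled over folds

  // without per-fold scaling, distances are fold-invariant: compute the
  // full sample-by-sample matrix once per subset and slice it per fold
  bool need_dist = false;
  for (int c = 0; c < nclf; ++c)
    if (classifiers[(size_t) c] == "SVM" || classifiers[(size_t) c] == "KNN")
      need_dist = true;
  mat Dall;
  if (need_dist && !scale) Dall = pairwise_sqdist(X, X);

  bool need_tree = false;
  for (int c = 0; c < nclf; ++c)
    if (classifiers[(size_t) c] == "DTree") need_tree = true;
  std::vector<std::vector<int>> gorder;
  if (need_tree && !scale) gorder = feature_orders(X, std::vector<char>());

  for (int f = 1; f <= nfold; ++f) {
    uvec tr = arma::find(fold != f), te = arma::find(fold == f);
    if (te.n_elem == 0) continue;
    mat Xtr = X.rows(tr), Xte = X.rows(te);
    ivec ytr = y.elem(tr), yte = y.elem(te);
    if (scale) scale_train_test(Xtr, Xte);

    for (int c = 0; c < nclf; ++c) {
      const std::string& name = classifiers[(size_t) c];
      ivec pred;
      if (!scale && name == "KNN") {
        pred = knn_from_dist(Dall.submat(te, tr), ytr);
      } else if (!scale && name == "SVM") {
        pred = svm_from_dist(Dall.submat(tr, tr), Dall.submat(te, tr), ytr,
                             rbf_gamma(Xtr));
      } else if (!scale && name == "DTree") {
        // grow on the full-sample index space, root lists filtered to the
        // training samples of this fold (reuses the global presort)
        std::vector<std::vector<int>> order(gorder.size());
        for (size_t j = 0; j < gorder.size(); ++j) {
          order[j].reserve(tr.n_elem);
          for (int s : gorder[j])
            if (fold((arma::uword) s) != f) order[j].push_back(s);
        }
        std::vector<TreeNode> nodes;
        int root = tree_grow(nodes, X, y, order, 0);
        pred = dtree_predict_nodes(nodes, root, X.rows(te));
      } else {
        pred = predict_by_name(name, Xtr, ytr, Xte);
      }
      for (arma::uword i = 0; i < te.n_elem; ++i) {
        if (yte(i) == 1) {
          if (pred(i) == 1) counts(c, 0) += 1; else counts(c, 1) += 1;
        } else {
          if (pred(i) == 1) counts(c, 2) += 1; else counts(c, 3) += 1;
        }
      }
    }
  }
  return counts;
}

// [[Rcpp::export(name = ".builtin_predict_cpp")]]
Rcpp::IntegerVector builtin_predict_cpp(const std::string& name,
                                        const arma::mat& Xtr,
                                        const arma::ivec& ytr,
                                        const arma::mat& Xte) {
  ivec out = predict_by_name(name, Xtr, ytr, Xte);
  return Rcpp::wrap(arma::conv_to<std::vector<int>>::from(out));
}
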