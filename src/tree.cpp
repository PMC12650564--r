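// Exact-greedy regression tree (variance-reduction splits) used as the
// base learner for the random-forest and gradient-boosting regressors.
// Feature subsampling at each split (mtry) uses R's RNG stream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;
};

static int grow(const mat& X, const vec& y, std::vector<int>& rows,
                int depth, int max_depth, int min_node, int mtry,
                TreeNodes& T) {
  const int node = T.feature.size();
  T.feature.push_back(-1); T.threshold.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1);
  double ysum = 0.0;
  for (int r : rows) ysum += y[r];
  const int nr = rows.size();
  T.value.push_back(ysum / nr);

  if (depth >= max_depth || nr < 2 * min_node) return node;

  // candidate features: mtry sampled without replacement
  const int p = X.n_cols;
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(R::unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(feats[i], feats[j]);
  }

  double best_gain = 1e-12;
  int best_f = -1; double best_thr = 0.0;
  double sse_parent_num = 0.0; // use sum-of-squares decomposition
  for (int r : rows) sse_parent_num += y[r] * y[r];
  const double parent_score = ysum * ysum / nr;

  std::vector<std::pair<double,double>> xy(nr);
  for (int fi = 0; fi < m; ++fi) {
    const int f = feats[fi];
    for (int i = 0; i < nr; ++i)
      xy[i] = std::make_pair(X(rows[i], f), y[rows[i]]);
    std::sort(xy.begin(), xy.end());
    double lsum = 0.0;
    for (int i = 0; i < nr - 1; ++i) {
      lsum += xy[i].second;
      if (xy[i].first == xy[i + 1].first) continue;
      int nl = i + 1, nrr = nr - nl;
      if (nl < min_node || nrr < min_node) continue;
      double rsum = ysum - lsum;
      double gain = lsum * lsum / nl + rsum * rsum / nrr - parent_score;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  std::vector<int> lrows, rrows;
  for (int r : rows) {
    if (X(r, best_f) <= best_thr) lrows.push_back(r);
    else rrows.push_back(r);
  }
  if (lrows.empty() || rrows.empty()) return node;
  T.feature[node] = best_f;
  T.threshold[node] = best_thr;
  T.left[node] = grow(X, y, lrows, depth + 1, max_depth, min_node, mtry, T);
  T.right[node] = grow(X, y, rrows, depth + 1, max_depth, min_node, mtry, T);
  return node;
}

// [[Rcpp::export]]
Rcpp::List tree_fit_cpp(const arma::mat& X, const arma::vec& y,
                        const arma::ivec& rows, int max_depth, int min_node,
                        int mtry) {
  TreeNodes T;
  std::vector<int> rr(rows.n_elem);
  for (uword i = 0; i < rows.n_elem; ++i) rr[i] = rows[i];
  grow(X, y, rr, 0, max_depth, min_node, mtry, T);
  return Rcpp::List::create(
    Rcpp::Named("feature") = Rcpp::wrap(T.feature),
    Rcpp::Named("threshold") = Rcpp::wrap(T.threshold),
    Rcpp::Named("left") = Rcpp::wrap(T.left),
    Rcpp::Named("right") = Rcpp::wrap(T.right),
    Rcpp::Named("value") = Rcpp::wrap(T.value));
}

// [[Rcpp::export]]
arma::vec tree_predict_cpp(const Rcpp::List& tree, const arma::mat& X) {
  Rcpp::IntegerVector feature = tree["feature"];
  Rcpp::NumericVector threshold = tree["threshold"];
  Rcpp::IntegerVector left = tree["left"], right = tree["right"];
  Rcpp::NumericVector value = tree["value"];
  const int n = X.n_rows;
  vec out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ?
        left[node] : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
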