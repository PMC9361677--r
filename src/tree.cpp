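// Decision-tree engine shared by the random forest, SAMME AdaBoost and the
// two second-order gradient boosters (depth-wise and leaf-wise growth).
//
// mode 0: weighted-Gini classification tree; needs y in {0,1} and weights w;
//         leaf value = weighted class-1 fraction.
// mode 1: regression tree on (gradient, hessian) pairs with L2 shrinkage
//         reg_lambda and L1 soft-thresholding reg_alpha on the leaf score;
//         leaf value = -T(G)/(H + lambda); split gain =
//         (score_L + score_R - score_P)/2.
//
// Growth is best-first (largest gain next) under both a depth cap and a leaf
// cap, so a depth-wise booster is max_leaves = INT_MAX / small max_depth and
// a leaf-wise booster is max_leaves = 31 / loose max_depth.

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct SplitResult {
  double gain = 0.0;
  int feature = -1;
  double threshold = 0.0;
};

struct NodeTask {
  int node_id;
  int depth;
  std::vector<int> rows;
  SplitResult split;
};

struct CmpGain {
  bool operator()(const NodeTask& a, const NodeTask& b) const {
    return a.split.gain < b.split.gain;
  }
};

inline double soft_threshold(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

class TreeBuilder {
 public:
  TreeBuilder(const NumericMatrix& X, int mode, const NumericVector& y,
              const NumericVector& w, const NumericVector& g,
              const NumericVector& h, int max_depth, int max_leaves,
              int min_samples_split, int min_samples_leaf, int max_features,
              double reg_lambda, double reg_alpha, unsigned int seed)
      : X_(X), mode_(mode), y_(y), w_(w), g_(g), h_(h),
        max_depth_(max_depth), max_leaves_(max_leaves),
        min_samples_split_(min_samples_split),
        min_samples_leaf_(min_samples_leaf), max_features_(max_features),
        reg_lambda_(reg_lambda), reg_alpha_(reg_alpha), rng_(seed),
        importance_(X.ncol(), 0.0) {}

  // node arrays
  std::vector<int> feature_, left_, right_;
  std::vector<double> threshold_, value_;
  std::vector<double> importance_;

  void build(const std::vector<int>& root_rows) {
    int root = new_node(leaf_value(root_rows));
    NodeTask t{root, 0, root_rows, SplitResult()};
    t.split = best_split(t.rows, t.depth);
    std::priority_queue<NodeTask, std::vector<NodeTask>, CmpGain> queue;
    if (t.split.feature >= 0) queue.push(std::move(t));
    int n_leaves = 1;
    while (!queue.empty() && n_leaves < max_leaves_) {
      NodeTask cur = queue.top();
      queue.pop();
      const int f = cur.split.feature;
      const double thr = cur.split.threshold;
      std::vector<int> lrows, rrows;
      lrows.reserve(cur.rows.size());
      rrows.reserve(cur.rows.size());
      for (int i : cur.rows) {
        if (X_(i, f) <= thr) lrows.push_back(i); else rrows.push_back(i);
      }
      if (lrows.size() < (size_t)min_samples_leaf_ ||
          rrows.size() < (size_t)min_samples_leaf_) continue;
      int lid = new_node(leaf_value(lrows));
      int rid = new_node(leaf_value(rrows));
      feature_[cur.node_id] = f;
      threshold_[cur.node_id] = thr;
      left_[cur.node_id] = lid;
      right_[cur.node_id] = rid;
      importance_[f] += cur.split.gain;
      ++n_leaves;
      NodeTask lt{lid, cur.depth + 1, std::move(lrows), SplitResult()};
      NodeTask rt{rid, cur.depth + 1, std::move(rrows), SplitResult()};
      lt.split = best_split(lt.rows, lt.depth);
      rt.split = best_split(rt.rows, rt.depth);
      if (lt.split.feature >= 0) queue.push(std::move(lt));
      if (rt.split.feature >= 0) queue.push(std::move(rt));
    }
  }

 private:
  const NumericMatrix& X_;
  int mode_;
  const NumericVector &y_, &w_, &g_, &h_;
  int max_depth_, max_leaves_, min_samples_split_, min_samples_leaf_,
      max_features_;
  double reg_lambda_, reg_alpha_;
  std::mt19937 rng_;

  int new_node(double value) {
    feature_.push_back(-1);
    threshold_.push_back(0.0);
    left_.push_back(-1);
    right_.push_back(-1);
    value_.push_back(value);
    return (int)feature_.size() - 1;
  }

  double leaf_value(const std::vector<int>& rows) const {
    if (mode_ == 0) {
      double sw = 0.0, swy = 0.0;
      for (int i : rows) { sw += w_[i]; swy += w_[i] * y_[i]; }
      return sw > 0 ? swy / sw : 0.5;
    }
    double G = 0.0, H = 0.0;
    for (int i : rows) { G += g_[i]; H += h_[i]; }
    return -soft_threshold(G, reg_alpha_) / (H + reg_lambda_);
  }

  double node_score(double G, double H) const {
    double t = soft_threshold(G, reg_alpha_);
    return t * t / (H + reg_lambda_);
  }

  std::vector<int> sample_features() {
    const int p = X_.ncol();
    int m = (max_features_ <= 0 || max_features_ >= p) ? p : max_features_;
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    if (m < p) {  // partial Fisher-Yates
      for (int j = 0; j < m; ++j) {
        std::uniform_int_distribution<int> d(j, p - 1);
        std::swap(feats[j], feats[d(rng_)]);
      }
      feats.resize(m);
      std::sort(feats.begin(), feats.end());
    }
    return feats;
  }

  SplitResult best_split(const std::vector<int>& rows, int depth) {
    SplitResult best;
    const int n = (int)rows.size();
    if (depth >= max_depth_ || n < min_samples_split_ || n < 2) return best;

    double swT = 0.0, swyT = 0.0, GT = 0.0, HT = 0.0;
    if (mode_ == 0) {
      for (int i : rows) { swT += w_[i]; swyT += w_[i] * y_[i]; }
      if (swT <= 0 || swyT <= 1e-15 || swT - swyT <= 1e-15) return best;
    } else {
      for (int i : rows) { GT += g_[i]; HT += h_[i]; }
    }
    const double parent_imp =
        (mode_ == 0) ? 2.0 * swyT * (swT - swyT) / swT : 0.0;
    const double parent_score = (mode_ == 1) ? node_score(GT, HT) : 0.0;

    std::vector<int> feats = sample_features();
    std::vector<std::pair<double, int> > vals(n);
    for (int f : feats) {
      for (int k = 0; k < n; ++k) {
        vals[k] = std::make_pair(X_(rows[k], f), rows[k]);
      }
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      double sw = 0.0, swy = 0.0, G = 0.0, H = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        const int i = vals[k].second;
        if (mode_ == 0) { sw += w_[i]; swy += w_[i] * y_[i]; }
        else { G += g_[i]; H += h_[i]; }
        if (vals[k].first == vals[k + 1].first) continue;
        if (k + 1 < min_samples_leaf_ || n - k - 1 < min_samples_leaf_)
          continue;
        double gain;
        if (mode_ == 0) {
          const double swr = swT - sw, swyr = swyT - swy;
          const double li = sw > 0 ? 2.0 * swy * (sw - swy) / sw : 0.0;
          const double ri = swr > 0 ? 2.0 * swyr * (swr - swyr) / swr : 0.0;
          gain = parent_imp - li - ri;
        } else {
          gain = 0.5 * (node_score(G, H) + node_score(GT - G, HT - H) -
                        parent_score);
        }
        if (gain > best.gain + 1e-12) {
          best.gain = gain;
          best.feature = f;
          best.threshold = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best.gain <= 1e-12) best.feature = -1;
    return best;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, int mode, NumericVector y,
                   NumericVector w, NumericVector g, NumericVector h,
                   IntegerVector rows, int max_depth, int max_leaves,
                   int min_samples_split, int min_samples_leaf,
                   int max_features, double reg_lambda, double reg_alpha,
                   int seed) {
  std::vector<int> root_rows(rows.begin(), rows.end());
  TreeBuilder tb(X, mode, y, w, g, h, max_depth, max_leaves,
                 min_samples_split, min_samples_leaf, max_features,
                 reg_lambda, reg_alpha, (unsigned int)seed);
  tb.build(root_rows);
  return List::create(
      _["feature"] = wrap(tb.feature_), _["threshold"] = wrap(tb.threshold_),
      _["left"] = wrap(tb.left_), _["right"] = wrap(tb.right_),
      _["value"] = wrap(tb.value_), _["importance"] = wrap(tb.importance_));
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
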