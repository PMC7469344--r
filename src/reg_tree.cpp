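#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Greedy least-squares regression tree used as the base learner of the
// gradient booster. Grown depth-first to a maximum depth with deterministic
// tie-breaking: among splits with equal improvement the lowest feature index
// wins, and within a feature the lowest threshold. Zero-improvement splits
// are taken (necessary so that interactions such as XOR, invisible to any
// single split, can still be reached at depth >= 2); nodes with zero
// residual variance are closed early.

struct Node {
  int feature;      // -1 for leaf
  double threshold; // x <= threshold goes left
  int left, right;  // node indices, -1 if leaf
  double value;     // mean residual in node
  int n;
};

static void grow(const NumericMatrix& X, const NumericVector& r,
                 std::vector<int>& rows, int depth, int max_depth,
                 int min_split, int min_bucket,
                 std::vector<Node>& nodes, int node_id,
                 IntegerVector& leaf_of) {
  const int n = rows.size();
  double sum = 0.0, sum2 = 0.0;
  for (int i = 0; i < n; ++i) { sum += r[rows[i]]; sum2 += r[rows[i]] * r[rows[i]]; }
  nodes[node_id].value = sum / n;
  nodes[node_id].n = n;
  double ss = sum2 - sum * sum / n;

  bool can_split = depth < max_depth && n >= min_split && ss > 1e-12;
  int best_j = -1, best_cut = -1;
  double best_imp = -1.0, best_thr = 0.0;

  if (can_split) {
    std::vector<std::pair<double, double> > xv(n); // (x, r)
    for (int j = 0; j < X.ncol(); ++j) {
      for (int i = 0; i < n; ++i) xv[i] = std::make_pair(X(rows[i], j), r[rows[i]]);
      std::stable_sort(xv.begin(), xv.end());
      if (xv[0].first == xv[n - 1].first) continue; // constant feature
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += xv[i].second;
        if (xv[i].first == xv[i + 1].first) continue; // not a boundary
        int nl = i + 1, nr = n - nl;
        if (nl < min_bucket || nr < min_bucket) continue;
        double sr = sum - sl;
        double imp = sl * sl / nl + sr * sr / nr - sum * sum / n;
        // strict '>' keeps the first (lowest feature, lowest threshold) on ties
        if (imp > best_imp + 1e-12) {
          best_imp = imp;
          best_j = j;
          best_cut = i;
          best_thr = (xv[i].first + xv[i + 1].first) / 2.0;
        }
      }
    }
  }

  if (best_j < 0 || best_imp < -1e-12) { // leaf
    nodes[node_id].feature = -1;
    for (int i = 0; i < n; ++i) leaf_of[rows[i]] = node_id;
    return;
  }

  std::vector<int> lrows, rrows;
  lrows.reserve(n); rrows.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (X(rows[i], best_j) <= best_thr) lrows.push_back(rows[i]);
    else rrows.push_back(rows[i]);
  }

  nodes[node_id].feature = best_j;
  nodes[node_id].threshold = best_thr;
  int li = nodes.size();
  nodes.push_back(Node()); nodes.push_back(Node());
  nodes[node_id].left = li;
  nodes[node_id].right = li + 1;
  grow(X, r, lrows, depth + 1, max_depth, min_split, min_bucket, nodes, li, leaf_of);
  grow(X, r, rrows, depth + 1, max_depth, min_split, min_bucket, nodes, li + 1, leaf_of);
}

// [[Rcpp::export(name = ".fitRegTree")]]
List fit_reg_tree(NumericMatrix X, NumericVector r,
                  int max_depth = 3, int min_split = 2, int min_bucket = 1) {
  const int n = X.nrow();
  std::vector<Node> nodes;
  nodes.reserve(64);
  nodes.push_back(Node());
  IntegerVector leaf_of(n);
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  grow(X, r, rows, 0, max_depth, min_split, min_bucket, nodes, 0, leaf_of);

  const int m = nodes.size();
  IntegerVector feature(m), left(m), right(m), nn(m);
  NumericVector threshold(m), value(m);
  for (int k = 0; k < m; ++k) {
    feature[k] = nodes[k].feature;           // -1 marks a leaf
    threshold[k] = nodes[k].feature < 0 ? NA_REAL : nodes[k].threshold;
    left[k] = nodes[k].feature < 0 ? -1 : nodes[k].left;
    right[k] = nodes[k].feature < 0 ? -1 : nodes[k].right;
    value[k] = nodes[k].value;
    nn[k] = nodes[k].n;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value, _["n"] = nn,
                      _["leaf_of"] = leaf_of);
}

// [[Rcpp::export(name = ".predictRegTree")]]
NumericVector predict_reg_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
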