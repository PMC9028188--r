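#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Deterministic axis-aligned CART with Gini impurity, used as the base
// learner of the time series forest. Each feature is sorted once at the
// root; splits partition the per-feature sorted index lists in linear time
// (the classic presort strategy), so growing cost is O(p n log n + p n d).
// Ties between equally good splits break toward the lower feature index,
// then the lower threshold, so the same inputs always yield the same tree.

struct Node {
  int var;          // split feature (-1 for leaf)
  double threshold; // x[var] <= threshold goes left
  int left, right;  // child node ids (-1 for leaf)
  int pred;         // majority class (0-based)
  int n;            // samples in node
};

class Grower {
public:
  const NumericMatrix& X;
  const IntegerVector& y;
  int K, minsplit, minbucket, maxdepth;
  std::vector<Node> nodes;

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int K_,
         int minsplit_, int minbucket_, int maxdepth_)
    : X(X_), y(y_), K(K_), minsplit(minsplit_), minbucket(minbucket_),
      maxdepth(maxdepth_) {}

  int grow(std::vector<std::vector<int> >& order, int depth) {
    int p = (int)order.size();
    int m = (int)order[0].size();

    std::vector<int> cnt(K, 0);
    for (int i = 0; i < m; ++i) cnt[y[order[0][i]]]++;

    int id = (int)nodes.size();
    Node nd;
    nd.var = -1;
    nd.threshold = 0.0;
    nd.left = nd.right = -1;
    nd.n = m;
    nd.pred = 0;
    for (int k = 1; k < K; ++k) if (cnt[k] > cnt[nd.pred]) nd.pred = k;
    nodes.push_back(nd);

    double imp = 1.0;
    for (int k = 0; k < K; ++k) {
      double q = (double)cnt[k] / m;
      imp -= q * q;
    }
    if (m < minsplit || imp <= 0.0 || depth >= maxdepth) return id;

    int best_var = -1;
    double best_thr = 0.0;
    // maximize suml/nl + sumr/nr, where sum* are sums of squared class
    // counts; equivalent to maximizing the Gini gain but O(1) per position
    double sumsq_all = 0.0;
    for (int k = 0; k < K; ++k) sumsq_all += (double)cnt[k] * cnt[k];
    double best_score = sumsq_all / m + 1e-9;
    std::vector<int> lcnt(K);
    const double* xbase = &X(0, 0);
    int nrow = X.nrow();

    for (int j = 0; j < p; ++j) {
      const std::vector<int>& ord = order[j];
      const double* xj = xbase + (size_t)j * nrow;
      std::fill(lcnt.begin(), lcnt.end(), 0);
      double suml = 0.0, sumr = sumsq_all;
      for (int i = 0; i < m - 1; ++i) {
        int c = y[ord[i]];
        int rc = cnt[c] - lcnt[c]; // right count of c before the move
        suml += 2.0 * lcnt[c] + 1.0;
        sumr -= 2.0 * rc - 1.0;
        lcnt[c]++;
        double xi = xj[ord[i]], xn = xj[ord[i + 1]];
        if (xi == xn) continue;
        int nl = i + 1, nr = m - nl;
        if (nl < minbucket || nr < minbucket) continue;
        double score = suml / nl + sumr / nr;
        if (score > best_score + 1e-9) {
          best_score = score;
          best_var = j;
          best_thr = 0.5 * (xi + xn);
        }
      }
    }
    if (best_var < 0) return id;

    // partition every feature's sorted list, preserving order
    std::vector<std::vector<int> > lord(p), rord(p);
    for (int j = 0; j < p; ++j) {
      lord[j].reserve(m);
      rord[j].reserve(m);
      for (int i = 0; i < m; ++i) {
        int idx = order[j][i];
        if (X(idx, best_var) <= best_thr) lord[j].push_back(idx);
        else rord[j].push_back(idx);
      }
    }
    if (lord[0].empty() || rord[0].empty()) return id; // degenerate
    order.clear();
    order.shrink_to_fit();

    int lid = grow(lord, depth + 1);
    { std::vector<std::vector<int> > tmp; lord.swap(tmp); }
    int rid = grow(rord, depth + 1);

    nodes[id].var = best_var;
    nodes[id].threshold = best_thr;
    nodes[id].left = lid;
    nodes[id].right = rid;
    return id;
  }
};

// [[Rcpp::export(name = ".cart_grow")]]
List cart_grow(NumericMatrix X, IntegerVector y, int n_classes,
               int minsplit, int minbucket, int maxdepth) {
  int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<int> > order(p);
  std::vector<std::pair<double, int> > vals(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(i, j), i);
    std::sort(vals.begin(), vals.end());
    order[j].resize(n);
    for (int i = 0; i < n; ++i) order[j][i] = vals[i].second;
  }

  Grower g(X, y, n_classes, minsplit, minbucket, maxdepth);
  g.grow(order, 0);

  int nn = (int)g.nodes.size();
  IntegerVector var(nn), left(nn), right(nn), pred(nn), nvec(nn);
  NumericVector thr(nn);
  for (int i = 0; i < nn; ++i) {
    var[i] = g.nodes[i].var;
    thr[i] = g.nodes[i].threshold;
    left[i] = g.nodes[i].left;
    right[i] = g.nodes[i].right;
    pred[i] = g.nodes[i].pred;
    nvec[i] = g.nodes[i].n;
  }
  return List::create(_["var"] = var, _["threshold"] = thr,
                      _["left"] = left, _["right"] = right,
                      _["pred"] = pred, _["n"] = nvec);
}

// [[Rcpp::export(name = ".cart_predict")]]
IntegerVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"],
                pred = tree["pred"];
  NumericVector thr = tree["threshold"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (var[node] >= 0)
      node = (X(i, var[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = pred[node];
  }
  return out;
}
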