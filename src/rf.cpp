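#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Bagged CART classification forest for binary labels coded 0/1.
// Gini-impurity splits over `mtry` features sampled without replacement at
// each node; nodes become leaves when pure or when they hold <= nodesize
// cases. All randomness is drawn from R's RNG stream so that forests are
// reproducible under set.seed().

namespace {

struct Node {
  int feature;       // -1 marks a leaf
  double threshold;  // x[feature] <= threshold goes left
  int left, right;
  int pred;          // majority class at the node (tie -> 0)
};

inline int randInt(int n) {
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

class Tree {
public:
  std::vector<Node> nodes;

  Tree(const NumericMatrix& X, const IntegerVector& y,
       const std::vector<int>& sample, int mtry, int nodesize)
      : X_(X), y_(y), mtry_(mtry), nodesize_(nodesize), pool_(X.ncol()) {
    for (int j = 0; j < X.ncol(); ++j) pool_[j] = j;
    std::vector<int> idx(sample);
    build(idx);
  }

  int predictRow(const NumericMatrix& X, int i) const {
    int k = 0;
    while (nodes[k].feature >= 0)
      k = (X(i, nodes[k].feature) <= nodes[k].threshold) ? nodes[k].left
                                                         : nodes[k].right;
    return nodes[k].pred;
  }

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int mtry_, nodesize_;
  std::vector<int> pool_;

  int build(std::vector<int>& idx) {
    const int n = idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y_[i];
    const int id = nodes.size();
    Node nd;
    nd.feature = -1;
    nd.threshold = 0.0;
    nd.left = nd.right = -1;
    nd.pred = (2 * n1 > n) ? 1 : 0;
    nodes.push_back(nd);
    if (n1 == 0 || n1 == n || n < 2 || n <= nodesize_) return id;

    // parent weighted impurity: n * gini
    const double parent =
        n - (double)(n - n1) * (n - n1) / n - (double)n1 * n1 / n;
    double bestScore = parent - 1e-12;
    int bestF = -1;
    double bestT = 0.0;

    // sample mtry distinct features (partial Fisher-Yates on the pool)
    const int p = pool_.size();
    for (int t = 0; t < mtry_; ++t) {
      int u = t + randInt(p - t);
      std::swap(pool_[t], pool_[u]);
    }

    std::vector<std::pair<double, int>> xv(n);
    for (int t = 0; t < mtry_; ++t) {
      const int f = pool_[t];
      for (int k = 0; k < n; ++k) xv[k] = {X_(idx[k], f), y_[idx[k]]};
      std::sort(xv.begin(), xv.end());
      if (xv.front().first == xv.back().first) continue;
      int l1 = 0;
      for (int k = 0; k < n - 1; ++k) {
        l1 += xv[k].second;
        if (xv[k].first == xv[k + 1].first) continue;
        const int nl = k + 1, nr = n - nl;
        const int r1 = n1 - l1;
        const double score =
            nl - (double)(nl - l1) * (nl - l1) / nl - (double)l1 * l1 / nl +
            nr - (double)(nr - r1) * (nr - r1) / nr - (double)r1 * r1 / nr;
        if (score < bestScore) {
          bestScore = score;
          bestF = f;
          bestT = 0.5 * (xv[k].first + xv[k + 1].first);
        }
      }
    }
    if (bestF < 0) return id;

    std::vector<int> lidx, ridx;
    lidx.reserve(n);
    ridx.reserve(n);
    for (int i : idx)
      (X_(i, bestF) <= bestT ? lidx : ridx).push_back(i);
    // degenerate split guard (threshold between ties)
    if (lidx.empty() || ridx.empty()) return id;
    idx.clear();
    idx.shrink_to_fit();
    const int lid = build(lidx);
    const int rid = build(ridx);
    nodes[id].feature = bestF;
    nodes[id].threshold = bestT;
    nodes[id].left = lid;
    nodes[id].right = rid;
    return id;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_train_predict_cpp")]]
IntegerVector rf_train_predict_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                   NumericMatrix Xte, int ntree, int mtry,
                                   int nodesize) {
  const int n = Xtr.nrow(), m = Xte.nrow();
  if (mtry < 1 || mtry > Xtr.ncol()) stop("mtry out of range");
  if (nodesize < 1) stop("nodesize must be >= 1");
  if (ntree < 1) stop("ntree must be >= 1");
  std::vector<int> votes(m, 0);
  std::vector<int> boot(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) boot[i] = randInt(n);
    Tree tree(Xtr, ytr, boot, mtry, nodesize);
    for (int i = 0; i < m; ++i) votes[i] += tree.predictRow(Xte, i);
  }
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) out[i] = (2 * votes[i] > ntree) ? 1 : 0;
  return out;
}
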