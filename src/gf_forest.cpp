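// Bagged-regression-tree engine behind the turnover model.
//
// One forest per locus: bootstrap rows, recursive variance-reduction
// splitting over a random mtry-subset of variables, every split's impurity
// reduction recorded with its variable and threshold (the raw material of
// the turnover functions), and out-of-bag R^2 for the locus weight.
// Uses R's RNG throughout so a set.seed() in R makes the fit reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Acc {
  std::vector<int> var;
  std::vector<double> thr, imp;
};

struct Node {
  bool leaf;
  double value, thr;
  int var, left, right;
};

class Tree {
public:
  const NumericMatrix &X;
  const NumericVector &y;
  int mtry, min_split;
  Acc &acc;
  std::vector<Node> nodes;

  Tree(const NumericMatrix &X_, const NumericVector &y_, int mtry_,
       int min_split_, Acc &acc_)
      : X(X_), y(y_), mtry(mtry_), min_split(min_split_), acc(acc_) {}

  int grow(const std::vector<int> &rows) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    int n = (int)rows.size();
    double sum = 0.0;
    for (int r : rows) sum += y[r];
    double mean = sum / n;
    bool constant = true;
    for (int r : rows)
      if (y[r] != y[rows[0]]) { constant = false; break; }
    if (n < min_split || constant) {
      nodes[id] = {true, mean, 0.0, -1, -1, -1};
      return id;
    }
    int V = X.ncol();
    std::vector<int> vars(V);
    for (int v = 0; v < V; ++v) vars[v] = v;
    int ntry = std::min(mtry, V);
    for (int k = 0; k < ntry; ++k) {  // partial Fisher-Yates via R RNG
      int j = k + (int)(unif_rand() * (V - k));
      if (j >= V) j = V - 1;
      std::swap(vars[k], vars[j]);
    }
    int best_var = -1;
    double best_thr = 0.0, best_gain = 0.0;
    std::vector<std::pair<double, double>> xy(n);
    for (int k = 0; k < ntry; ++k) {
      int v = vars[k];
      for (int i = 0; i < n; ++i)
        xy[i] = std::make_pair(X(rows[i], v), y[rows[i]]);
      std::sort(xy.begin(), xy.end());
      double tot = 0.0;
      for (int i = 0; i < n; ++i) tot += xy[i].second;
      double cs = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        cs += xy[i].second;
        if (xy[i + 1].first <= xy[i].first) continue;
        double nl = i + 1, nr = n - nl;
        double gain = cs * cs / nl + (tot - cs) * (tot - cs) / nr
                      - tot * tot / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_var = v;
          best_thr = (xy[i].first + xy[i + 1].first) / 2.0;
        }
      }
    }
    if (best_var < 0 || best_gain <= 0.0) {
      nodes[id] = {true, mean, 0.0, -1, -1, -1};
      return id;
    }
    acc.var.push_back(best_var + 1);  // 1-based for R
    acc.thr.push_back(best_thr);
    acc.imp.push_back(best_gain);
    std::vector<int> lrows, rrows;
    for (int r : rows)
      (X(r, best_var) <= best_thr ? lrows : rrows).push_back(r);
    int l = grow(lrows);
    int rr = grow(rrows);
    nodes[id].leaf = false;
    nodes[id].value = mean;
    nodes[id].var = best_var;
    nodes[id].thr = best_thr;
    nodes[id].left = l;
    nodes[id].right = rr;
    return id;
  }

  double predict(int row) const {
    int id = 0;
    while (!nodes[id].leaf)
      id = (X(row, nodes[id].var) <= nodes[id].thr) ? nodes[id].left
                                                    : nodes[id].right;
    return nodes[id].value;
  }
};

}  // namespace

// [[Rcpp::export(name = ".gf_forest_cpp")]]
List gf_forest_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                   int min_split) {
  int n = y.size();
  Acc acc;
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<char> inbag(n);
  std::vector<int> bag;
  bag.reserve(n);
  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    bag.clear();
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j >= n) j = n - 1;
      bag.push_back(j);
      inbag[j] = 1;
    }
    Tree tree(X, y, mtry, min_split, acc);
    tree.grow(bag);
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) {
        oob_sum[i] += tree.predict(i);
        oob_cnt[i]++;
      }
  }
  double my = 0.0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  double vy = 0.0;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy /= (n - 1);
  double mse = 0.0;
  int m = 0;
  for (int i = 0; i < n; ++i)
    if (oob_cnt[i] > 0) {
      double e = y[i] - oob_sum[i] / oob_cnt[i];
      mse += e * e;
      ++m;
    }
  double r2 = 0.0;
  if (m > 0 && vy > 0.0) {
    r2 = 1.0 - (mse / m) / vy;
    if (r2 < 0.0) r2 = 0.0;
  }
  return List::create(_["var"] = acc.var, _["thr"] = acc.thr,
                      _["imp"] = acc.imp, _["r2"] = r2);
}
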