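// Classification-tree ensemble over binary haplotype alleles.
//
// Trees are CART-style with two-way splits (predictors are 0/1 phased
// alleles), Gini impurity, per-node random attribute subspaces, and
// bootstrap bagging at the ensemble level.  All randomness comes from an
// internal mt19937 stream so that fits are bit-identical for a given seed
// regardless of the R session's RNG state.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

typedef std::mt19937 rng_t;

// uniform integer in [0, n); avoids std::uniform_int_distribution whose
// output sequence is not standardised across library implementations
inline int rand_below(rng_t &rng, int n) {
  return static_cast<int>(rng() % static_cast<unsigned>(n));
}

struct TreeBuf {
  std::vector<int> var;    // split SNP index, -1 for leaf
  std::vector<int> left;   // child node index for allele 0
  std::vector<int> right;  // child node index for allele 1
  std::vector<int> pred;   // leaf class, -1 for internal
};

// Majority class among idx (bootstrap multiplicity included); ties go to the
// smallest class index, i.e. canonical sorted label order on the R side.
int majority_class(const std::vector<int> &idx, const int *y, int nclass,
                   std::vector<int> &cnt) {
  std::fill(cnt.begin(), cnt.end(), 0);
  for (int i : idx) cnt[y[i]]++;
  int best = 0;
  for (int c = 1; c < nclass; c++)
    if (cnt[c] > cnt[best]) best = c;
  return best;
}

// Split score to maximise: sum_children sum_c count_c^2 / n_child.
// Maximising this is equivalent to minimising the weighted child Gini
// impurity.  Kept in this exact form (two divisions, one addition) so an
// exhaustive R-side search with the same formula reproduces it bitwise.
struct SplitSearch {
  int best_var;
  double best_score;
};

void grow_tree(const int *X, int n, int p, const int *y, int nclass,
               int mtry, int max_nodes, rng_t &rng,
               std::vector<int> &sample_idx, TreeBuf &tree) {
  tree.var.clear(); tree.left.clear(); tree.right.clear(); tree.pred.clear();

  std::vector<int> cnt(nclass), cntl(nclass);
  std::vector<int> pool(p);
  std::vector<int> cand(mtry);

  // stack of (node id, begin, end) over a shared index buffer
  std::vector<int> idx = sample_idx;
  struct Job { int node, lo, hi; };
  std::vector<Job> stack;

  tree.var.push_back(-1); tree.left.push_back(-1);
  tree.right.push_back(-1); tree.pred.push_back(-1);
  stack.push_back({0, 0, (int)idx.size()});

  while (!stack.empty()) {
    Job job = stack.back(); stack.pop_back();
    int nn = job.hi - job.lo;

    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = job.lo; i < job.hi; i++) cnt[y[idx[i]]]++;
    int top = 0;
    for (int c = 1; c < nclass; c++) if (cnt[c] > cnt[top]) top = c;

    bool pure = (cnt[top] == nn);
    bool room = (max_nodes <= 0) ||
                ((int)tree.var.size() + 2 <= max_nodes);
    int chosen = -1;
    double best_score = 0.0;

    if (!pure && room && nn >= 2) {
      // draw mtry candidate SNPs without replacement, then examine them in
      // ascending index order so exact score ties resolve to the smallest
      // SNP index independent of draw order
      for (int j = 0; j < p; j++) pool[j] = j;
      for (int j = 0; j < mtry; j++) {
        int k = j + rand_below(rng, p - j);
        std::swap(pool[j], pool[k]);
        cand[j] = pool[j];
      }
      std::sort(cand.begin(), cand.begin() + mtry);

      double ss_par = 0.0;
      for (int c = 0; c < nclass; c++)
        ss_par += (double)cnt[c] * cnt[c];
      double score_par = ss_par / nn;

      for (int j = 0; j < mtry; j++) {
        int v = cand[j];
        std::fill(cntl.begin(), cntl.end(), 0);
        int nl = 0;
        for (int i = job.lo; i < job.hi; i++) {
          if (X[(size_t)idx[i] + (size_t)v * n] == 0) { cntl[y[idx[i]]]++; nl++; }
        }
        int nr = nn - nl;
        if (nl == 0 || nr == 0) continue;
        double ssl = 0.0, ssr = 0.0;
        for (int c = 0; c < nclass; c++) {
          double cl = cntl[c], cr = cnt[c] - cntl[c];
          ssl += cl * cl; ssr += cr * cr;
        }
        double score = ssl / nl + ssr / nr;
        if (score > score_par + 1e-12 && (chosen < 0 || score > best_score)) {
          chosen = v; best_score = score;
        }
      }
    }

    if (chosen < 0) {
      tree.var[job.node] = -1;
      tree.pred[job.node] = top;
      continue;
    }

    // partition idx[lo,hi) on allele of chosen SNP (0 left, 1 right)
    int i = job.lo, jx = job.hi - 1;
    while (i <= jx) {
      if (X[(size_t)idx[i] + (size_t)chosen * n] == 0) i++;
      else std::swap(idx[i], idx[jx--]);
    }
    int mid = i;

    int lnode = tree.var.size();
    tree.var.push_back(-1); tree.left.push_back(-1);
    tree.right.push_back(-1); tree.pred.push_back(-1);
    int rnode = tree.var.size();
    tree.var.push_back(-1); tree.left.push_back(-1);
    tree.right.push_back(-1); tree.pred.push_back(-1);

    tree.var[job.node] = chosen;
    tree.left[job.node] = lnode;
    tree.right[job.node] = rnode;
    stack.push_back({lnode, job.lo, mid});
    stack.push_back({rnode, mid, job.hi});
  }
}

inline int tree_predict_row(const IntegerVector &var, const IntegerVector &left,
                            const IntegerVector &right, const IntegerVector &pred,
                            const int *xrow, int n, int row) {
  int node = 0;
  while (var[node] >= 0) {
    int a = xrow[(size_t)row + (size_t)var[node] * n];
    node = (a == 0) ? left[node] : right[node];
  }
  return pred[node];
}

// predict one row with the values of SNP v overridden by x_override
inline int tree_predict_override(const IntegerVector &var, const IntegerVector &left,
                                 const IntegerVector &right, const IntegerVector &pred,
                                 const int *X, int n, int row, int v, int x_override) {
  int node = 0;
  while (var[node] >= 0) {
    int sv = var[node];
    int a = (sv == v) ? x_override : X[(size_t)row + (size_t)sv * n];
    node = (a == 0) ? left[node] : right[node];
  }
  return pred[node];
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_fit(IntegerMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, int max_nodes, int seed, bool bag) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, n_snps]");
  rng_t rng(static_cast<unsigned>(seed));

  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  std::vector<int> sample_idx(n);
  TreeBuf buf;

  for (int t = 0; t < ntree; t++) {
    if (bag) {
      for (int i = 0; i < n; i++) {
        int k = rand_below(rng, n);
        sample_idx[i] = k;
        inbag(k, t)++;
      }
    } else {
      for (int i = 0; i < n; i++) { sample_idx[i] = i; inbag(i, t) = 1; }
    }
    grow_tree(X.begin(), n, p, y.begin(), nclass, mtry, max_nodes, rng,
              sample_idx, buf);
    trees[t] = List::create(_["var"] = wrap(buf.var), _["left"] = wrap(buf.left),
                            _["right"] = wrap(buf.right), _["pred"] = wrap(buf.pred));
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export]]
IntegerMatrix cpp_rf_votes(List trees, IntegerMatrix X, int nclass) {
  int n = X.nrow(), ntree = trees.size();
  IntegerMatrix votes(n, nclass);
  for (int t = 0; t < ntree; t++) {
    List tr = trees[t];
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"],
                  pred = tr["pred"];
    for (int i = 0; i < n; i++) {
      int c = tree_predict_row(var, left, right, pred, X.begin(), n, i);
      votes(i, c)++;
    }
  }
  return votes;
}

// [[Rcpp::export]]
IntegerMatrix cpp_rf_oob_votes(List trees, IntegerMatrix inbag, IntegerMatrix X,
                               int nclass) {
  int n = X.nrow(), ntree = trees.size();
  IntegerMatrix votes(n, nclass);
  for (int t = 0; t < ntree; t++) {
    List tr = trees[t];
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"],
                  pred = tr["pred"];
    for (int i = 0; i < n; i++) {
      if (inbag(i, t) != 0) continue;
      int c = tree_predict_row(var, left, right, pred, X.begin(), n, i);
      votes(i, c)++;
    }
  }
  return votes;
}

// Breiman permutation importance: for every tree, compare OOB accuracy on the
// actual data with OOB accuracy after permuting one SNP's alleles within the
// tree's OOB set (one fresh permutation per tree x SNP).  Score = mean drop /
// SD of drops (mean alone when the SD is zero, which leaves never-used SNPs
// at exactly 0).
// [[Rcpp::export]]
List cpp_rf_importance(List trees, IntegerMatrix inbag, IntegerMatrix X,
                       IntegerVector y, int seed) {
  int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  rng_t rng(static_cast<unsigned>(seed));

  std::vector<double> sum_drop(p, 0.0), sumsq_drop(p, 0.0);
  int used_trees = 0;
  std::vector<int> oob;
  std::vector<char> used(p);
  std::vector<int> perm;

  for (int t = 0; t < ntree; t++) {
    List tr = trees[t];
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"],
                  pred = tr["pred"];
    oob.clear();
    for (int i = 0; i < n; i++) if (inbag(i, t) == 0) oob.push_back(i);
    int m = oob.size();
    if (m == 0) continue;
    used_trees++;

    std::fill(used.begin(), used.end(), 0);
    for (int k = 0; k < var.size(); k++) if (var[k] >= 0) used[var[k]] = 1;

    int correct0 = 0;
    for (int i : oob)
      if (tree_predict_row(var, left, right, pred, X.begin(), n, i) == y[i])
        correct0++;
    double acc0 = (double)correct0 / m;

    for (int v = 0; v < p; v++) {
      if (!used[v]) continue;  // identical predictions, drop exactly 0
      perm.resize(m);
      for (int i = 0; i < m; i++) perm[i] = oob[i];
      for (int i = m - 1; i > 0; i--) {
        int k = rand_below(rng, i + 1);
        std::swap(perm[i], perm[k]);
      }
      int correct1 = 0;
      for (int i = 0; i < m; i++) {
        int xov = X((size_t)perm[i], v);
        if (tree_predict_override(var, left, right, pred, X.begin(), n,
                                  oob[i], v, xov) == y[oob[i]])
          correct1++;
      }
      double drop = acc0 - (double)correct1 / m;
      sum_drop[v] += drop;
      sumsq_drop[v] += drop * drop;
    }
  }

  NumericVector mean_drop(p), sd_drop(p), score(p);
  for (int v = 0; v < p; v++) {
    if (used_trees == 0) { mean_drop[v] = 0; sd_drop[v] = 0; score[v] = 0; continue; }
    double mu = sum_drop[v] / used_trees;
    double varr = used_trees > 1
      ? std::max(0.0, (sumsq_drop[v] - used_trees * mu * mu) / (used_trees - 1))
      : 0.0;
    double sd = std::sqrt(varr);
    mean_drop[v] = mu;
    sd_drop[v] = sd;
    score[v] = sd > 0 ? mu / sd : mu;
  }
  return List::create(_["mean_drop"] = mean_drop, _["sd_drop"] = sd_drop,
                      _["score"] = score, _["n_trees_used"] = used_trees);
}
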