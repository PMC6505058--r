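// Oblique classification random forest.
//
// Each internal node draws `mtry` features without replacement, regresses the
// +/-1 coded class labels on that subset by ridge (L2-penalised) least
// squares for every candidate penalty, and places a threshold on the ridge
// projection at the midpoint minimising the Gini impurity of the induced
// split. Trees are grown on bootstrap samples of size n; out-of-bag votes
// give the generalisation estimate used for hyperparameter tuning.
//
// The bootstrapped importance score refits forests on resamples of the data
// and, at every internal node, fits a logistic regression of the node labels
// on the node's feature subset: each subset feature scores +1 when its Wald
// p-value is below `alpha`, -1 otherwise. All randomness comes from R's RNG
// so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double BIG_DEPTH = 1e9;

// m distinct integers from 0..p-1 via partial Fisher-Yates on R's RNG
std::vector<int> sample_features(int p, int m) {
  std::vector<int> pool(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  std::vector<int> out(m);
  for (int i = 0; i < m; ++i) {
    int j = i + (int)std::floor(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
  return out;
}

struct Node {
  int left = -1, right = -1;   // -1 => leaf
  int cls = -1;                // leaf class
  int n = 0;                   // training samples reaching the node
  double thr = 0.0;
  std::vector<int> feat;       // feature subset (empty for leaves)
  arma::vec w;                 // intercept + subset weights
};

struct GrowParams {
  int mtry;
  int min_node;
  double max_depth;
  const arma::vec *lambdas;
  double alpha;
  bool do_importance;
  bool univariate;
  arma::vec *imp_score;
  int *imp_flagged;
};

int majority_class(const arma::ivec &y, const arma::uvec &rows) {
  int ones = 0;
  for (arma::uword i = 0; i < rows.n_elem; ++i) ones += y(rows(i));
  int zeros = (int)rows.n_elem - ones;
  return ones >= zeros ? 1 : 0; // tie -> positive class (conversion)
}

// Wald p-values for non-intercept columns of a logistic fit; returns false
// on non-convergence / (quasi-)separation.
bool logistic_wald(const arma::mat &A, const arma::vec &y01, arma::vec &pvals) {
  const arma::uword q = A.n_cols;
  arma::vec beta(q, arma::fill::zeros);
  arma::mat H;
  bool converged = false;
  for (int it = 0; it < 30; ++it) {
    arma::vec eta = arma::clamp(A * beta, -30.0, 30.0);
    arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec wv = p % (1.0 - p);
    for (arma::uword i = 0; i < wv.n_elem; ++i) if (wv(i) < 1e-10) wv(i) = 1e-10;
    H = A.t() * (A.each_col() % wv);
    H.diag() += 1e-10;
    arma::vec g = A.t() * (y01 - p);
    arma::vec delta;
    if (!arma::solve(delta, H, g, arma::solve_opts::likely_sympd + arma::solve_opts::no_approx))
      return false;
    beta += delta;
    if (arma::abs(delta).max() < 1e-8) { converged = true; break; }
  }
  if (!converged) return false;
  for (arma::uword j = 1; j < q; ++j)
    if (std::abs(beta(j)) > 15.0) return false; // separation on standardized scale
  arma::mat cov;
  if (!arma::inv_sympd(cov, H)) return false;
  pvals.set_size(q - 1);
  for (arma::uword j = 1; j < q; ++j) {
    double se = std::sqrt(cov(j, j));
    if (!std::isfinite(se) || se <= 0) return false;
    double z = beta(j) / se;
    pvals(j - 1) = 2.0 * R::pnorm(-std::abs(z), 0.0, 1.0, 1, 0);
  }
  return true;
}

void node_importance(const arma::mat &A, const arma::vec &y01,
                     const std::vector<int> &feat, const GrowParams &gp) {
  if (gp.univariate) {
    for (size_t j = 0; j < feat.size(); ++j) {
      arma::mat Aj(A.n_rows, 2);
      Aj.col(0).ones();
      Aj.col(1) = A.col(j + 1);
      arma::vec pv;
      if (logistic_wald(Aj, y01, pv))
        (*gp.imp_score)(feat[j]) += (pv(0) < gp.alpha) ? 1.0 : -1.0;
      else { (*gp.imp_score)(feat[j]) += 1.0; ++(*gp.imp_flagged); }
    }
    return;
  }
  arma::vec pv;
  if (logistic_wald(A, y01, pv)) {
    for (size_t j = 0; j < feat.size(); ++j)
      (*gp.imp_score)(feat[j]) += (pv(j) < gp.alpha) ? 1.0 : -1.0;
  } else {
    for (size_t j = 0; j < feat.size(); ++j) (*gp.imp_score)(feat[j]) += 1.0;
    ++(*gp.imp_flagged);
  }
}

int grow(std::vector<Node> &nodes, const arma::mat &X, const arma::ivec &y,
         const arma::uvec &rows, int depth, const GrowParams &gp) {
  const int me = (int)nodes.size();
  nodes.push_back(Node());
  nodes[me].n = (int)rows.n_elem;

  const int nr = (int)rows.n_elem;
  int ones = 0;
  for (int i = 0; i < nr; ++i) ones += y(rows(i));
  const int zeros = nr - ones;

  bool make_leaf = (ones == 0 || zeros == 0 || nr < gp.min_node || depth >= gp.max_depth);
  if (!make_leaf) {
    const int p = (int)X.n_cols;
    const int m = std::min(gp.mtry, p);
    std::vector<int> feat = sample_features(p, m);
    arma::uvec sub(m);
    for (int j = 0; j < m; ++j) sub(j) = feat[j];

    arma::mat A(nr, m + 1);
    A.col(0).ones();
    A.cols(1, m) = X.submat(rows, sub);
    arma::vec ypm(nr);
    for (int i = 0; i < nr; ++i) ypm(i) = y(rows(i)) == 1 ? 1.0 : -1.0;
    arma::mat AtA = A.t() * A;
    arma::vec Aty = A.t() * ypm;

    const double p1 = (double)ones / nr, p0 = (double)zeros / nr;
    const double parent_gini = 1.0 - p1 * p1 - p0 * p0;

    double best_gini = parent_gini - 1e-12;
    bool found = false;
    arma::vec best_w;
    double best_thr = 0.0;
    arma::vec best_proj;

    for (arma::uword li = 0; li < gp.lambdas->n_elem; ++li) {
      arma::mat M = AtA;
      for (int j = 1; j <= m; ++j) M(j, j) += (*gp.lambdas)(li); // intercept unpenalised
      arma::vec beta;
      if (!arma::solve(beta, M, Aty, arma::solve_opts::likely_sympd + arma::solve_opts::no_approx))
        beta = arma::pinv(M) * Aty;
      arma::vec proj = A * beta;
      arma::uvec ord = arma::stable_sort_index(proj);
      // sweep candidate thresholds at midpoints of distinct sorted projections
      int onesL = 0;
      for (int i = 0; i < nr - 1; ++i) {
        onesL += y(rows(ord(i)));
        double lo = proj(ord(i)), hi = proj(ord(i + 1));
        if (hi - lo <= 1e-12) continue;
        int nL = i + 1, nR = nr - nL;
        int zerosL = nL - onesL;
        int onesR = ones - onesL, zerosR = zeros - zerosL;
        double gL = 1.0 - ((double)onesL * onesL + (double)zerosL * zerosL) / ((double)nL * nL);
        double gR = 1.0 - ((double)onesR * onesR + (double)zerosR * zerosR) / ((double)nR * nR);
        double g = (nL * gL + nR * gR) / nr;
        if (g < best_gini) {
          best_gini = g;
          best_thr = 0.5 * (lo + hi);
          best_w = beta;
          best_proj = proj;
          found = true;
        }
      }
    }

    if (found) {
      if (gp.do_importance) {
        arma::vec y01(nr);
        for (int i = 0; i < nr; ++i) y01(i) = (double)y(rows(i));
        node_importance(A, y01, feat, gp);
      }
      std::vector<arma::uword> li, ri;
      li.reserve(nr); ri.reserve(nr);
      for (int i = 0; i < nr; ++i) {
        if (best_proj(i) <= best_thr) li.push_back(rows(i)); else ri.push_back(rows(i));
      }
      arma::uvec lrows(li.data(), li.size()), rrows(ri.data(), ri.size());
      nodes[me].feat = feat;
      nodes[me].w = best_w;
      nodes[me].thr = best_thr;
      int l = grow(nodes, X, y, lrows, depth + 1, gp);
      int r = grow(nodes, X, y, rrows, depth + 1, gp);
      nodes[me].left = l;
      nodes[me].right = r;
      return me;
    }
  }
  nodes[me].cls = majority_class(y, rows);
  return me;
}

int tree_predict_one(const std::vector<Node> &nodes, const arma::rowvec &x) {
  int cur = 0;
  while (nodes[cur].left >= 0) {
    const Node &nd = nodes[cur];
    double s = nd.w(0);
    for (size_t j = 0; j < nd.feat.size(); ++j) s += nd.w(j + 1) * x(nd.feat[j]);
    cur = (s <= nd.thr) ? nd.left : nd.right;
  }
  return nodes[cur].cls;
}

List tree_to_list(const std::vector<Node> &nodes) {
  const int k = (int)nodes.size();
  IntegerVector left(k), right(k), cls(k), nn(k);
  NumericVector thr(k);
  List subsets(k), weights(k);
  for (int i = 0; i < k; ++i) {
    left[i] = nodes[i].left; right[i] = nodes[i].right;
    cls[i] = nodes[i].cls;   nn[i] = nodes[i].n;
    thr[i] = nodes[i].thr;
    if (nodes[i].left >= 0) {
      subsets[i] = IntegerVector(nodes[i].feat.begin(), nodes[i].feat.end());
      weights[i] = NumericVector(nodes[i].w.begin(), nodes[i].w.end());
    } else {
      subsets[i] = IntegerVector(0);
      weights[i] = NumericVector(0);
    }
  }
  return List::create(_["left"] = left, _["right"] = right, _["class"] = cls,
                      _["n"] = nn, _["threshold"] = thr,
                      _["subsets"] = subsets, _["weights"] = weights);
}

std::vector<Node> tree_from_list(const List &tr) {
  IntegerVector left = tr["left"], right = tr["right"], cls = tr["class"], nn = tr["n"];
  NumericVector thr = tr["threshold"];
  List subsets = tr["subsets"], weights = tr["weights"];
  std::vector<Node> nodes(left.size());
  for (int i = 0; i < left.size(); ++i) {
    nodes[i].left = left[i]; nodes[i].right = right[i];
    nodes[i].cls = cls[i];   nodes[i].n = nn[i];
    nodes[i].thr = thr[i];
    IntegerVector fs = subsets[i];
    NumericVector ws = weights[i];
    nodes[i].feat.assign(fs.begin(), fs.end());
    nodes[i].w = arma::vec(ws.begin(), ws.size());
  }
  return nodes;
}

void fit_forest_internal(const arma::mat &X, const arma::ivec &y, int ntree,
                         const GrowParams &gp, std::vector<std::vector<Node>> &trees,
                         arma::imat &inbag) {
  const int n = (int)X.n_rows;
  trees.clear();
  trees.reserve(ntree);
  inbag.zeros(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    arma::uvec rows(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)std::floor(unif_rand() * n);
      if (j >= n) j = n - 1;
      rows(i) = j;
      inbag(j, t) += 1;
    }
    std::vector<Node> nodes;
    grow(nodes, X, y, rows, 0, gp);
    trees.push_back(std::move(nodes));
  }
}

} // namespace

// [[Rcpp::export]]
List orf_fit_cpp(const arma::mat &X, const arma::ivec &y, int mtry, int ntree,
                 const arma::vec &lambdas, int min_node = 2, int max_depth = 0) {
  const int n = (int)X.n_rows;
  GrowParams gp;
  gp.mtry = mtry; gp.min_node = std::max(min_node, 2);
  gp.max_depth = max_depth > 0 ? (double)max_depth : BIG_DEPTH;
  gp.lambdas = &lambdas; gp.alpha = 0.05;
  gp.do_importance = false; gp.univariate = false;
  gp.imp_score = nullptr; gp.imp_flagged = nullptr;

  std::vector<std::vector<Node>> trees;
  arma::imat inbag;
  fit_forest_internal(X, y, ntree, gp, trees, inbag);

  // out-of-bag majority vote (tie -> positive class)
  IntegerVector oob_pred(n, NA_INTEGER);
  int oob_wrong = 0, oob_n = 0;
  for (int i = 0; i < n; ++i) {
    int v1 = 0, v0 = 0;
    arma::rowvec xi = X.row(i);
    for (int t = 0; t < ntree; ++t) {
      if (inbag(i, t) != 0) continue;
      if (tree_predict_one(trees[t], xi) == 1) ++v1; else ++v0;
    }
    if (v1 + v0 == 0) continue;
    int pred = (v1 >= v0) ? 1 : 0;
    oob_pred[i] = pred;
    ++oob_n;
    if (pred != y(i)) ++oob_wrong;
  }
  double oob_error = oob_n > 0 ? (double)oob_wrong / oob_n : NA_REAL;

  List rtrees(ntree);
  for (int t = 0; t < ntree; ++t) rtrees[t] = tree_to_list(trees[t]);
  return List::create(_["trees"] = rtrees, _["oob_error"] = oob_error,
                      _["oob_pred"] = oob_pred,
                      _["inbag"] = wrap(inbag));
}

// [[Rcpp::export]]
NumericVector orf_vote_cpp(const List &rtrees, const arma::mat &X) {
  const int ntree = rtrees.size();
  const int n = (int)X.n_rows;
  std::vector<std::vector<Node>> trees(ntree);
  for (int t = 0; t < ntree; ++t) trees[t] = tree_from_list(rtrees[t]);
  NumericVector frac(n);
  for (int i = 0; i < n; ++i) {
    arma::rowvec xi = X.row(i);
    int v1 = 0;
    for (int t = 0; t < ntree; ++t)
      if (tree_predict_one(trees[t], xi) == 1) ++v1;
    frac[i] = (double)v1 / ntree;
  }
  return frac;
}

// [[Rcpp::export]]
List orf_importance_cpp(const arma::mat &X, const arma::ivec &y, int mtry,
                        int ntree, const arma::vec &lambdas, int n_bootstrap = 100,
                        double alpha = 0.05, bool univariate = false,
                        int min_node = 2, int max_depth = 0) {
  const int n = (int)X.n_rows, p = (int)X.n_cols;
  arma::vec score(p, arma::fill::zeros);
  int flagged = 0;
  GrowParams gp;
  gp.mtry = mtry; gp.min_node = std::max(min_node, 2);
  gp.max_depth = max_depth > 0 ? (double)max_depth : BIG_DEPTH;
  gp.lambdas = &lambdas; gp.alpha = alpha;
  gp.do_importance = true; gp.univariate = univariate;
  gp.imp_score = &score; gp.imp_flagged = &flagged;

  for (int b = 0; b < n_bootstrap; ++b) {
    // bootstrap resample of the data set, then a forest on top of it
    arma::uvec bidx(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)std::floor(unif_rand() * n);
      if (j >= n) j = n - 1;
      bidx(i) = j;
    }
    arma::mat Xb = X.rows(bidx);
    arma::ivec yb(n);
    for (int i = 0; i < n; ++i) yb(i) = y(bidx(i));
    std::vector<std::vector<Node>> trees;
    arma::imat inbag;
    fit_forest_internal(Xb, yb, ntree, gp, trees, inbag);
  }
  return List::create(_["total_score"] = wrap(score),
                      _["mean_score"] = wrap(arma::vec(score / (double)n_bootstrap)),
                      _["n_flagged_nodes"] = flagged);
}
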