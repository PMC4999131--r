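#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <map>
#include <cstdint>
using namespace Rcpp;

// Conditional inference regression trees: split variables are chosen by the
// p-value of a standardized linear association statistic between candidate
// predictor and response within the node (permutation variance), with a
// Bonferroni-adjusted stop criterion.  Categorical predictors enter through
// their level indicators (max standardized statistic, Bonferroni over
// levels) and split by level subsets along the ordering of level means.
// All randomness is drawn from R's RNG so results are reproducible from
// set.seed() on the R side.

namespace {

struct Node {
  int var;        // -1 for leaf
  double thr;     // numeric threshold: x <= thr goes left
  double mask;    // categorical: bitmask of level codes going left
  int left, right;
  double pred;    // node mean of y (prediction when leaf)
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> oob;
};

inline int rint(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// two-sided p-value of the standardized linear statistic sum((x-xbar)*(y-ybar))
inline double assoc_pval(double sxy, double sxx, double syy, int m) {
  if (sxx <= 0.0 || syy <= 0.0 || m < 2) return 1.0;
  double z2 = sxy * sxy * (double)(m - 1) / (sxx * syy);
  return R::pchisq(z2, 1.0, 0, 0);
}

class Builder {
public:
  const NumericMatrix &X;
  const NumericVector &y;
  const IntegerVector &nlev;   // 0 for numeric predictors, L for categorical
  int p, mtry, minsplit, minbucket;
  double alpha;
  std::vector<Node> nodes;
  std::vector<int> cand;

  Builder(const NumericMatrix &X_, const NumericVector &y_,
          const IntegerVector &nlev_, int mtry_, double alpha_,
          int minsplit_, int minbucket_)
    : X(X_), y(y_), nlev(nlev_), p(X_.ncol()), mtry(mtry_),
      minsplit(minsplit_), minbucket(minbucket_), alpha(alpha_) {
    cand.resize(p);
    for (int j = 0; j < p; ++j) cand[j] = j;
  }

  int build(std::vector<int> &obs) {
    int m = (int)obs.size();
    double ysum = 0.0;
    for (int i : obs) ysum += y[i];
    double ybar = ysum / m;
    double syy = 0.0;
    for (int i : obs) { double d = y[i] - ybar; syy += d * d; }

    int id = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, 0.0, -1, -1, ybar});
    if (m < minsplit || syy <= 0.0) return id;

    // sample mtry candidate predictors without replacement
    int k = std::min(mtry, p);
    for (int j = 0; j < k; ++j) std::swap(cand[j], cand[j + rint(p - j)]);
    std::vector<int> sel(cand.begin(), cand.begin() + k);

    int best = -1;
    double best_p = 2.0;
    for (int j : sel) {
      double pv = candidate_pval(j, obs, m, ybar, syy);
      if (pv < best_p) { best_p = pv; best = j; }
    }
    double p_adj = std::min(1.0, best_p * k);
    if (best < 0 || p_adj > alpha) return id;

    double thr = 0.0, mask = 0.0;
    std::vector<int> lobs, robs;
    bool ok = (nlev[best] > 0)
      ? split_categorical(best, obs, ybar, syy, mask, lobs, robs)
      : split_numeric(best, obs, ybar, syy, thr, lobs, robs);
    if (!ok) return id;

    nodes[id].var = best;
    nodes[id].thr = thr;
    nodes[id].mask = mask;
    int l = build(lobs);
    int r = build(robs);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

private:
  double candidate_pval(int j, const std::vector<int> &obs, int m,
                        double ybar, double syy) {
    if (nlev[j] == 0) {
      double xs = 0.0;
      for (int i : obs) xs += X(i, j);
      double xbar = xs / m, sxx = 0.0, sxy = 0.0;
      for (int i : obs) {
        double dx = X(i, j) - xbar;
        sxx += dx * dx;
        sxy += dx * (y[i] - ybar);
      }
      return assoc_pval(sxy, sxx, syy, m);
    }
    // categorical: max standardized level-indicator statistic, Bonferroni
    int L = nlev[j];
    std::vector<int> cnt(L + 1, 0);
    std::vector<double> ysuml(L + 1, 0.0);
    for (int i : obs) {
      int l = (int)X(i, j);
      cnt[l]++; ysuml[l] += y[i] - ybar;
    }
    double pmin = 1.0; int present = 0;
    for (int l = 1; l <= L; ++l) {
      if (cnt[l] == 0 || cnt[l] == m) continue;
      present++;
      double xbar = (double)cnt[l] / m;
      double sxx = cnt[l] * (1.0 - xbar) * (1.0 - xbar)
                 + (m - cnt[l]) * xbar * xbar;
      double pv = assoc_pval(ysuml[l], sxx, syy, m);
      if (pv < pmin) pmin = pv;
    }
    if (present == 0) return 1.0;
    return std::min(1.0, pmin * present);
  }

  // maximize |sum_left (y - ybar)| standardized over admissible cuts
  bool split_numeric(int j, std::vector<int> &obs, double ybar, double syy,
                     double &thr, std::vector<int> &lobs,
                     std::vector<int> &robs) {
    int m = (int)obs.size();
    std::vector<int> ord(obs);
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, j) < X(b, j);
    });
    double pref = 0.0, best_crit = -1.0;
    int best_nl = -1;
    for (int k = 0; k < m - 1; ++k) {
      pref += y[ord[k]] - ybar;
      int nl = k + 1;
      if (X(ord[k], j) == X(ord[k + 1], j)) continue;
      if (nl < minbucket || m - nl < minbucket) continue;
      double v = (double)nl * (m - nl) / ((double)m * (m - 1)) * syy;
      if (v <= 0.0) continue;
      double crit = pref * pref / v;
      if (crit > best_crit) { best_crit = crit; best_nl = nl; }
    }
    if (best_nl < 0) return false;
    thr = 0.5 * (X(ord[best_nl - 1], j) + X(ord[best_nl], j));
    for (int i : obs) (X(i, j) <= thr ? lobs : robs).push_back(i);
    return true;
  }

  // order levels by mean response, scan binary splits along that order
  bool split_categorical(int j, std::vector<int> &obs, double ybar,
                         double syy, double &mask, std::vector<int> &lobs,
                         std::vector<int> &robs) {
    int m = (int)obs.size(), L = nlev[j];
    std::vector<int> cnt(L + 1, 0);
    std::vector<double> ysuml(L + 1, 0.0);
    for (int i : obs) {
      int l = (int)X(i, j);
      cnt[l]++; ysuml[l] += y[i];
    }
    std::vector<int> lev;
    for (int l = 1; l <= L; ++l) if (cnt[l] > 0) lev.push_back(l);
    if ((int)lev.size() < 2) return false;
    std::sort(lev.begin(), lev.end(), [&](int a, int b) {
      return ysuml[a] / cnt[a] < ysuml[b] / cnt[b];
    });
    double pref = 0.0, best_crit = -1.0;
    int nl = 0, best_k = -1;
    for (size_t k = 0; k + 1 < lev.size(); ++k) {
      pref += ysuml[lev[k]] - cnt[lev[k]] * ybar;
      nl += cnt[lev[k]];
      if (nl < minbucket || m - nl < minbucket) continue;
      double v = (double)nl * (m - nl) / ((double)m * (m - 1)) * syy;
      if (v <= 0.0) continue;
      double crit = pref * pref / v;
      if (crit > best_crit) { best_crit = crit; best_k = (int)k; }
    }
    if (best_k < 0) return false;
    std::uint64_t bits = 0;
    for (int k = 0; k <= best_k; ++k) bits |= (std::uint64_t)1 << lev[k];
    mask = (double)bits;
    for (int i : obs) {
      int l = (int)X(i, j);
      ((bits >> l) & 1 ? lobs : robs).push_back(i);
    }
    return true;
  }
};

double predict_row(const std::vector<Node> &nodes, const NumericMatrix &X,
                   int i, const IntegerVector &nlev,
                   int override_var = -1, double override_val = 0.0) {
  int id = 0;
  while (nodes[id].var >= 0) {
    int j = nodes[id].var;
    double x = (j == override_var) ? override_val : X(i, j);
    bool go_left;
    if (nlev[j] > 0) {
      std::uint64_t bits = (std::uint64_t)nodes[id].mask;
      go_left = (bits >> (int)x) & 1;
    } else {
      go_left = x <= nodes[id].thr;
    }
    id = go_left ? nodes[id].left : nodes[id].right;
  }
  return nodes[id].pred;
}

std::vector<Node> unpack_tree(const List &tr) {
  IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
  NumericVector thr = tr["thr"], mask = tr["mask"], pred = tr["pred"];
  std::vector<Node> nodes(var.size());
  for (int i = 0; i < var.size(); ++i)
    nodes[i] = Node{var[i], thr[i], mask[i], left[i], right[i], pred[i]};
  return nodes;
}

} // namespace

// [[Rcpp::export(name = ".cif_fit_cpp")]]
List cif_fit_cpp(NumericMatrix X, NumericVector y, IntegerVector nlev,
                 int ntree, int mtry, double alpha, int minsplit,
                 int minbucket) {
  int n = X.nrow();
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<char> inbag(n, 0);
    std::vector<int> obs(n);
    for (int i = 0; i < n; ++i) {
      int d = rint(n);
      obs[i] = d;
      inbag[d] = 1;
    }
    Builder b(X, y, nlev, mtry, alpha, minsplit, minbucket);
    b.build(obs);
    int nn = (int)b.nodes.size();
    IntegerVector var(nn), left(nn), right(nn);
    NumericVector thr(nn), mask(nn), pred(nn);
    for (int i = 0; i < nn; ++i) {
      var[i] = b.nodes[i].var;   thr[i] = b.nodes[i].thr;
      mask[i] = b.nodes[i].mask; left[i] = b.nodes[i].left;
      right[i] = b.nodes[i].right; pred[i] = b.nodes[i].pred;
    }
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i + 1);
    trees[t] = List::create(_["var"] = var, _["thr"] = thr, _["mask"] = mask,
                            _["left"] = left, _["right"] = right,
                            _["pred"] = pred, _["oob"] = wrap(oob));
  }
  return trees;
}

// [[Rcpp::export(name = ".cif_predict_cpp")]]
NumericVector cif_predict_cpp(List trees, NumericMatrix X,
                              IntegerVector nlev) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    std::vector<Node> nodes = unpack_tree(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += predict_row(nodes, X, i, nlev);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// [[Rcpp::export(name = ".cif_oob_predict_cpp")]]
NumericVector cif_oob_predict_cpp(List trees, NumericMatrix X,
                                  IntegerVector nlev) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector sum(n, 0.0);
  IntegerVector cnt(n, 0);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    std::vector<Node> nodes = unpack_tree(tr);
    IntegerVector oob = tr["oob"];
    for (int k = 0; k < oob.size(); ++k) {
      int i = oob[k] - 1;
      sum[i] += predict_row(nodes, X, i, nlev);
      cnt[i]++;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cnt[i] > 0 ? sum[i] / cnt[i] : NA_REAL;
  return out;
}

// Permutation variable importance on out-of-bag observations.  For each
// predictor and tree, the predictor's OOB values are permuted -- freely for
// marginal importance, or within the cells of the partition induced by the
// tree's own split points on the predictor's conditioning covariates for
// conditional importance -- and the increase in OOB mean squared error over
// the unpermuted baseline is averaged over trees.
// cond_sets: list (length p) of integer vectors of 1-based covariate indices.
// [[Rcpp::export(name = ".cif_vi_cpp")]]
NumericVector cif_vi_cpp(List trees, NumericMatrix X, NumericVector y,
                         IntegerVector nlev, List cond_sets,
                         bool conditional) {
  int p = X.ncol(), ntree = trees.size();
  NumericVector vi(p, 0.0);
  IntegerVector used(p, 0);

  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    std::vector<Node> nodes = unpack_tree(tr);
    IntegerVector oob1 = tr["oob"];
    int no = oob1.size();
    if (no < 2) continue;
    std::vector<int> oob(no);
    for (int k = 0; k < no; ++k) oob[k] = oob1[k] - 1;

    // baseline OOB MSE for this tree
    double base = 0.0;
    for (int i : oob) {
      double e = y[i] - predict_row(nodes, X, i, nlev);
      base += e * e;
    }
    base /= no;

    // split thresholds used by this tree, per variable
    std::vector<std::vector<double> > cuts(p);
    for (const Node &nd : nodes)
      if (nd.var >= 0 && nlev[nd.var] == 0) cuts[nd.var].push_back(nd.thr);
    for (int j = 0; j < p; ++j) {
      std::sort(cuts[j].begin(), cuts[j].end());
      cuts[j].erase(std::unique(cuts[j].begin(), cuts[j].end()),
                    cuts[j].end());
    }

    for (int j = 0; j < p; ++j) {
      // stratum id per OOB observation
      std::map<long long, std::vector<int> > strata;
      if (conditional) {
        IntegerVector cs = cond_sets[j];
        for (int k = 0; k < no; ++k) {
          long long id = 0;
          for (int c = 0; c < cs.size(); ++c) {
            int v = cs[c] - 1;
            const std::vector<double> &cv = cuts[v];
            if (cv.empty()) continue;
            int idx = (int)(std::upper_bound(cv.begin(), cv.end(),
                                             X(oob[k], v)) - cv.begin());
            id = id * ((long long)cv.size() + 1) + idx;
          }
          strata[id].push_back(k);
        }
      } else {
        std::vector<int> all(no);
        for (int k = 0; k < no; ++k) all[k] = k;
        strata[0] = all;
      }

      // permute x_j within strata
      std::vector<double> xp(no);
      for (int k = 0; k < no; ++k) xp[k] = X(oob[k], j);
      for (auto &s : strata) {
        std::vector<int> &idx = s.second;
        for (int k = (int)idx.size() - 1; k > 0; --k) {
          int r = rint(k + 1);
          std::swap(xp[idx[k]], xp[idx[r]]);
        }
      }

      double mse = 0.0;
      for (int k = 0; k < no; ++k) {
        double e = y[oob[k]] - predict_row(nodes, X, oob[k], nlev, j, xp[k]);
        mse += e * e;
      }
      mse /= no;
      vi[j] += mse - base;
      used[j]++;
    }
  }
  for (int j = 0; j < p; ++j)
    vi[j] = used[j] > 0 ? vi[j] / used[j] : 0.0;
  return vi;
}

// [[Rcpp::export(name = ".cif_root_vars_cpp")]]
IntegerVector cif_root_vars_cpp(List trees) {
  IntegerVector out(trees.size());
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector var = tr["var"];
    out[t] = var[0] + 1; // 1-based; 0 -> leaf-only tree
  }
  return out;
}
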