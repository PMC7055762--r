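// Core tree learner for Newton (second-order) boosting on logistic loss.
//
// Trees are grown level-wise with exact greedy split search: candidate
// thresholds are the midpoints of consecutive distinct observed values of
// each feature within a node, and at every candidate both routings of
// missing values (left / right) are scored; an explicit present-vs-missing
// split is also offered.  Split gain is the usual second-order reduction
//   0.5 * [ GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda) ]
// with min_child_weight interpreted as the minimum hessian sum per child.
// Leaf weight = -G/(H+lambda).  Everything is deterministic: features are
// scanned in column order, thresholds in ascending order, and a candidate
// replaces the incumbent only on a strict gain improvement.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct SplitChoice {
  int feature = -1;          // 0-based column; -1 = no split
  double threshold = 0.0;    // midpoint; ignored for presence split
  bool presence = false;     // present-vs-missing split
  bool missing_left = true;  // routing of missing values (numeric split)
  double gain = 0.0;
  double GL = 0.0, HL = 0.0, GR = 0.0, HR = 0.0;
  int nL = 0, nR = 0;
};

inline double score(double G, double H, double lambda) {
  return (G * G) / (H + lambda);
}

}  // namespace

// Grow a single depth-limited tree on rows 0..n-1 of X.
//
// X:            n x p numeric matrix, NA = missing
// col_order:    list of p integer vectors, 0-based row indices with a
//               present value in that column, sorted ascending by value
// g, h:         per-row gradient / hessian at the current margin
// max_depth:    number of split levels (1 = stump)
// min_child_weight: minimum hessian sum per child
// lambda:       L2 leaf regularisation
//
// Returns a list of parallel vectors describing the nodes (1-based child
// indices, 0 for none; feature 0 marks a leaf; threshold NA marks a
// presence split).
// [[Rcpp::export]]
List lb_grow_tree(NumericMatrix X, List col_order, NumericVector g,
                  NumericVector h, int max_depth, double min_child_weight,
                  double lambda) {
  const int n = X.nrow();
  const int p = X.ncol();
  const double min_gain = 1e-12;

  // node arrays (grown as nodes are created)
  std::vector<double> nG, nH, nCover;
  std::vector<int> nFeat, nLeft, nRight, nCount, nDepth;
  std::vector<double> nThr, nVal, nGain;
  std::vector<bool> nPres, nMissLeft;

  auto new_node = [&](double G, double H, int cnt, int depth) -> int {
    nG.push_back(G); nH.push_back(H); nCount.push_back(cnt);
    nDepth.push_back(depth);
    nFeat.push_back(-1); nLeft.push_back(-1); nRight.push_back(-1);
    nThr.push_back(NA_REAL); nVal.push_back(NA_REAL); nGain.push_back(0.0);
    nPres.push_back(false); nMissLeft.push_back(true);
    nCover.push_back(H);
    return (int)nG.size() - 1;
  };

  double G0 = 0.0, H0 = 0.0;
  for (int i = 0; i < n; ++i) { G0 += g[i]; H0 += h[i]; }
  new_node(G0, H0, n, 0);

  std::vector<int> node_of(n, 0);
  std::vector<int> frontier(1, 0);  // node ids at the current level

  for (int depth = 0; depth < max_depth && !frontier.empty(); ++depth) {
    const int k = (int)frontier.size();
    // level-local index for each node id (-1 = not in frontier)
    std::vector<int> lvl(nG.size(), -1);
    for (int j = 0; j < k; ++j) lvl[frontier[j]] = j;

    std::vector<SplitChoice> best(k);

    std::vector<double> Gp(k), Hp(k), GL(k), HL(k), lastv(k);
    std::vector<int> np(k), cntL(k);

    for (int f = 0; f < p; ++f) {
      IntegerVector ord = col_order[f];
      const int m = ord.size();
      // pass A: per-node totals over present values of feature f
      std::fill(Gp.begin(), Gp.end(), 0.0);
      std::fill(Hp.begin(), Hp.end(), 0.0);
      std::fill(np.begin(), np.end(), 0);
      for (int ii = 0; ii < m; ++ii) {
        const int r = ord[ii];
        const int q = lvl[node_of[r]];
        if (q < 0) continue;
        Gp[q] += g[r]; Hp[q] += h[r]; ++np[q];
      }
      // pass B: scan thresholds in ascending order
      std::fill(GL.begin(), GL.end(), 0.0);
      std::fill(HL.begin(), HL.end(), 0.0);
      std::fill(cntL.begin(), cntL.end(), 0);
      for (int ii = 0; ii < m; ++ii) {
        const int r = ord[ii];
        const int q = lvl[node_of[r]];
        if (q < 0) continue;
        const int nid = frontier[q];
        const double v = X(r, f);
        if (cntL[q] > 0 && v > lastv[q]) {
          const double thr = lastv[q] + (v - lastv[q]) / 2.0;
          const double Gm = nG[nid] - Gp[q], Hm = nH[nid] - Hp[q];
          const int nm = nCount[nid] - np[q];
          // missing left, then missing right (first wins ties)
          for (int dir = 0; dir < 2; ++dir) {
            const bool ml = (dir == 0);
            const double gl = GL[q] + (ml ? Gm : 0.0);
            const double hl = HL[q] + (ml ? Hm : 0.0);
            const double gr = nG[nid] - gl, hr = nH[nid] - hl;
            const int cl = cntL[q] + (ml ? nm : 0);
            const int cr = nCount[nid] - cl;
            if (cl < 1 || cr < 1) continue;
            if (hl < min_child_weight || hr < min_child_weight) continue;
            const double gain = 0.5 * (score(gl, hl, lambda) +
                                       score(gr, hr, lambda) -
                                       score(nG[nid], nH[nid], lambda));
            if (gain > min_gain && gain > best[q].gain) {
              SplitChoice s;
              s.feature = f; s.threshold = thr; s.presence = false;
              s.missing_left = ml; s.gain = gain;
              s.GL = gl; s.HL = hl; s.GR = gr; s.HR = hr;
              s.nL = cl; s.nR = cr;
              best[q] = s;
            }
          }
        }
        GL[q] += g[r]; HL[q] += h[r]; ++cntL[q];
        lastv[q] = v;
      }
      // presence split: present -> left, missing -> right
      for (int q = 0; q < k; ++q) {
        const int nid = frontier[q];
        const double Gm = nG[nid] - Gp[q], Hm = nH[nid] - Hp[q];
        const int nm = nCount[nid] - np[q];
        if (np[q] < 1 || nm < 1) continue;
        if (Hp[q] < min_child_weight || Hm < min_child_weight) continue;
        const double gain = 0.5 * (score(Gp[q], Hp[q], lambda) +
                                   score(Gm, Hm, lambda) -
                                   score(nG[nid], nH[nid], lambda));
        if (gain > best[q].gain && gain > min_gain) {
          SplitChoice s;
          s.feature = f; s.presence = true; s.gain = gain;
          s.GL = Gp[q]; s.HL = Hp[q]; s.GR = Gm; s.HR = Hm;
          s.nL = np[q]; s.nR = nm;
          best[q] = s;
        }
      }
    }

    // apply splits, build next frontier
    std::vector<int> next;
    std::vector<int> lchild(k, -1), rchild(k, -1);
    for (int q = 0; q < k; ++q) {
      const int nid = frontier[q];
      const SplitChoice& s = best[q];
      if (s.feature < 0 || s.gain <= min_gain) continue;  // stays a leaf
      nFeat[nid] = s.feature;
      nThr[nid] = s.presence ? NA_REAL : s.threshold;
      nPres[nid] = s.presence;
      nMissLeft[nid] = s.missing_left;
      nGain[nid] = s.gain;
      lchild[q] = new_node(s.GL, s.HL, s.nL, depth + 1);
      rchild[q] = new_node(s.GR, s.HR, s.nR, depth + 1);
      nLeft[nid] = lchild[q];
      nRight[nid] = rchild[q];
      next.push_back(lchild[q]);
      next.push_back(rchild[q]);
    }
    // route rows of split nodes
    for (int r = 0; r < n; ++r) {
      const int q0 = lvl[node_of[r]];
      if (q0 < 0 || lchild[q0] < 0) continue;
      const int nid = frontier[q0];
      const double v = X(r, nFeat[nid]);
      bool left;
      if (nPres[nid]) {
        left = !NumericMatrix::is_na(v);
      } else if (NumericMatrix::is_na(v)) {
        left = nMissLeft[nid];
      } else {
        left = (v <= nThr[nid]);
      }
      node_of[r] = left ? lchild[q0] : rchild[q0];
    }
    frontier = next;
  }

  const int nn = (int)nG.size();
  IntegerVector feature(nn), left(nn), right(nn), count(nn);
  NumericVector threshold(nn), value(nn), gain(nn), cover(nn);
  LogicalVector presence(nn), missing_left(nn);
  for (int i = 0; i < nn; ++i) {
    const bool leaf = (nFeat[i] < 0);
    feature[i] = leaf ? 0 : nFeat[i] + 1;  // 1-based, 0 = leaf
    threshold[i] = nThr[i];
    presence[i] = nPres[i];
    missing_left[i] = nMissLeft[i];
    left[i] = leaf ? 0 : nLeft[i] + 1;
    right[i] = leaf ? 0 : nRight[i] + 1;
    value[i] = leaf ? (-nG[i] / (nH[i] + lambda)) : NA_REAL;
    gain[i] = leaf ? NA_REAL : nGain[i];
    cover[i] = nCover[i];
    count[i] = nCount[i];
  }
  return List::create(
      _["feature"] = feature, _["threshold"] = threshold,
      _["presence"] = presence, _["missing_left"] = missing_left,
      _["left"] = left, _["right"] = right, _["value"] = value,
      _["gain"] = gain, _["cover"] = cover, _["count"] = count);
}

namespace {

inline double tree_value(const IntegerVector& feature,
                         const NumericVector& threshold,
                         const LogicalVector& presence,
                         const LogicalVector& missing_left,
                         const IntegerVector& left, const IntegerVector& right,
                         const NumericVector& value, const NumericMatrix& X,
                         int row) {
  int node = 0;
  while (feature[node] != 0) {
    const double v = X(row, feature[node] - 1);
    bool go_left;
    if (presence[node]) {
      go_left = !NumericMatrix::is_na(v);
    } else if (NumericMatrix::is_na(v)) {
      go_left = missing_left[node];
    } else {
      go_left = (v <= threshold[node]);
    }
    node = (go_left ? left[node] : right[node]) - 1;
  }
  return value[node];
}

}  // namespace

// Raw (unscaled) leaf outputs of one tree for every row of X.
// [[Rcpp::export]]
NumericVector lb_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  LogicalVector presence = tree["presence"], missing_left =
      tree["missing_left"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = tree_value(feature, threshold, presence, missing_left, left,
                        right, value, X, i);
  return out;
}

// Margin of a whole ensemble: base_margin + lr * sum of tree outputs.
// [[Rcpp::export]]
NumericVector lb_predict_ensemble(List trees, NumericMatrix X,
                                  NumericVector base_margin, double lr) {
  const int n = X.nrow();
  NumericVector out(clone(base_margin));
  for (int t = 0; t < trees.size(); ++t) {
    List tree = trees[t];
    IntegerVector feature = tree["feature"], left = tree["left"],
                  right = tree["right"];
    NumericVector threshold = tree["threshold"], value = tree["value"];
    LogicalVector presence = tree["presence"], missing_left =
        tree["missing_left"];
    for (int i = 0; i < n; ++i)
      out[i] += lr * tree_value(feature, threshold, presence, missing_left,
                                left, right, value, X, i);
  }
  return out;
}
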