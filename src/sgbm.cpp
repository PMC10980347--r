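#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Stochastic gradient-boosted regression trees with squared-error loss,
// per-split feature subsampling, without-replacement row subsampling, and
// out-of-bag early stopping. Importance of a predictor is the total
// squared-error impurity reduction over all splits on it across retained
// stages (normalization happens in R).
//
// All randomness is drawn from R's RNG so results are reproducible under
// set.seed() and identical across platforms.

namespace {

struct Node {
  int feat;      // -1 for leaf
  double thr;    // split threshold (go left if x <= thr)
  double val;    // leaf prediction (mean residual)
  int left, right;
};

// k distinct integers from 0..n-1 (partial Fisher-Yates on a scratch pool)
void sampleWithoutReplacement(int n, int k, std::vector<int> &pool,
                              std::vector<int> &out) {
  for (int i = 0; i < n; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < k; ++i) {
    int j = i + static_cast<int>(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

struct Split {
  int feat = -1;
  double thr = 0.0;
  double gain = 0.0;
};

class TreeGrower {
public:
  TreeGrower(const NumericMatrix &X, const std::vector<double> &resid,
             int maxDepth, int mtry, std::vector<double> &imp)
      : X_(X), r_(resid), maxDepth_(maxDepth), mtry_(mtry), imp_(imp),
        p_(X.ncol()), featPool_(X.ncol()) {}

  // returns root node id; nodes_ holds the grown tree
  int grow(std::vector<int> &idx) {
    nodes_.clear();
    anySplit_ = false;
    return growNode(idx, 0);
  }

  double predict(int row) const {
    int cur = 0;
    while (nodes_[cur].feat >= 0) {
      cur = (X_(row, nodes_[cur].feat) <= nodes_[cur].thr) ? nodes_[cur].left
                                                           : nodes_[cur].right;
    }
    return nodes_[cur].val;
  }

  bool anySplit() const { return anySplit_; }

private:
  const NumericMatrix &X_;
  const std::vector<double> &r_;
  int maxDepth_, mtry_;
  std::vector<double> &imp_;
  int p_;
  std::vector<Node> nodes_;
  std::vector<int> featPool_, feats_;
  std::vector<std::pair<double, double> > buf_; // (x, residual) sorted by x
  bool anySplit_ = false;

  Split bestSplit(const std::vector<int> &idx) {
    Split best;
    const int n = static_cast<int>(idx.size());
    double sum = 0.0;
    for (int i = 0; i < n; ++i) sum += r_[idx[i]];
    const double parentTerm = sum * sum / n;

    sampleWithoutReplacement(p_, mtry_, featPool_, feats_);
    for (size_t f = 0; f < feats_.size(); ++f) {
      const int feat = feats_[f];
      buf_.clear();
      for (int i = 0; i < n; ++i)
        buf_.push_back(std::make_pair(X_(idx[i], feat), r_[idx[i]]));
      std::sort(buf_.begin(), buf_.end());
      if (buf_.front().first == buf_.back().first) continue; // constant feature
      double sumL = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sumL += buf_[i].second;
        if (buf_[i].first == buf_[i + 1].first) continue;
        const int nL = i + 1, nR = n - nL;
        const double sumR = sum - sumL;
        const double gain =
            sumL * sumL / nL + sumR * sumR / nR - parentTerm;
        if (gain > best.gain + 1e-15) {
          best.gain = gain;
          best.feat = feat;
          best.thr = 0.5 * (buf_[i].first + buf_[i + 1].first);
        }
      }
    }
    return best;
  }

  int growNode(std::vector<int> &idx, int depth) {
    const int n = static_cast<int>(idx.size());
    double sum = 0.0;
    for (int i = 0; i < n; ++i) sum += r_[idx[i]];
    Node node;
    node.feat = -1;
    node.thr = 0.0;
    node.val = sum / n;
    node.left = node.right = -1;

    if (depth < maxDepth_ && n >= 2) {
      Split sp = bestSplit(idx);
      if (sp.feat >= 0 && sp.gain > 1e-12) {
        imp_[sp.feat] += sp.gain;
        anySplit_ = true;
        std::vector<int> idxL, idxR;
        idxL.reserve(n);
        idxR.reserve(n);
        for (int i = 0; i < n; ++i) {
          if (X_(idx[i], sp.feat) <= sp.thr)
            idxL.push_back(idx[i]);
          else
            idxR.push_back(idx[i]);
        }
        node.feat = sp.feat;
        node.thr = sp.thr;
        const int self = static_cast<int>(nodes_.size());
        nodes_.push_back(node);
        nodes_[self].left = growNode(idxL, depth + 1);
        nodes_[self].right = growNode(idxR, depth + 1);
        return self;
      }
    }
    const int self = static_cast<int>(nodes_.size());
    nodes_.push_back(node);
    return self;
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".sgbm_fit")]]
List sgbmFit(NumericMatrix X, NumericVector y, double learningRate,
             int nStages, double subsample, double featFrac, int maxDepth,
             int window) {
  const int n = X.nrow(), p = X.ncol();
  if (n != y.size()) stop("length of y must match rows of X");

  double yMean = 0.0;
  for (int i = 0; i < n; ++i) yMean += y[i];
  yMean /= n;

  std::vector<double> resid(n);
  for (int i = 0; i < n; ++i) resid[i] = y[i] - yMean;

  int kIn = n;
  if (subsample < 1.0) {
    kIn = static_cast<int>(std::floor(subsample * n));
    if (kIn < 2) kIn = 2;
    if (kIn > n) kIn = n;
  }
  int mtry = static_cast<int>(std::floor(featFrac * p));
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  std::vector<double> imp(p, 0.0);
  std::vector<double> improvements;
  improvements.reserve(nStages);
  std::vector<int> rowPool(n), inIdx;
  std::vector<char> inBag(n);
  std::vector<double> pred(n);
  TreeGrower grower(X, resid, maxDepth, mtry, imp);

  int stagesUsed = 0;
  bool anySplit = false;

  for (int m = 0; m < nStages; ++m) {
    if (kIn < n) {
      sampleWithoutReplacement(n, kIn, rowPool, inIdx);
    } else {
      inIdx.resize(n);
      for (int i = 0; i < n; ++i) inIdx[i] = i;
    }
    std::fill(inBag.begin(), inBag.end(), 0);
    for (size_t i = 0; i < inIdx.size(); ++i) inBag[inIdx[i]] = 1;

    grower.grow(inIdx);
    anySplit = anySplit || grower.anySplit();

    for (int i = 0; i < n; ++i) pred[i] = grower.predict(i);

    // out-of-bag improvement in squared-error loss for this stage
    double oobImp = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!inBag[i]) {
        const double before = resid[i];
        const double after = resid[i] - learningRate * pred[i];
        oobImp += before * before - after * after;
      }
    }

    for (int i = 0; i < n; ++i) resid[i] -= learningRate * pred[i];

    improvements.push_back(oobImp);
    stagesUsed = m + 1;

    if (kIn < n && stagesUsed >= window) {
      double s = 0.0;
      for (int w = 0; w < window; ++w)
        s += improvements[stagesUsed - 1 - w];
      if (s <= 0.0) break;
    }
  }

  return List::create(Named("importance") = NumericVector(imp.begin(), imp.end()),
                      Named("stages") = stagesUsed,
                      Named("any_split") = anySplit);
}
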