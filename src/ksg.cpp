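// Nearest-neighbor (Kraskov-Stogbauer-Grassberger style) information
// estimators.  All distances are max-norm; marginal neighbor counts are
// strict (< eps, the distance to the k-th joint neighbor).  Returned in nats.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Minimal kd-tree over points stored column-wise (dim <= 3), max-norm.
// Supports k-th-neighbor distance (excluding the query point itself) and
// strict open-box range counting.
struct KdTree {
  const double* col[3];
  int dim, n;
  std::vector<int> idx;     // permutation; subtree = contiguous slice
  std::vector<int> splitdim;
  std::vector<double> splitval;
  // node layout: implicit recursion over slices, node id = slice encoding
  // we store per-slice split info in arrays indexed by node number
  struct Node { int lo, hi, d; double v; int left, right; };
  std::vector<Node> nodes;
  static const int LEAF = 16;

  void build(const double* const* cols, int dim_, int n_) {
    dim = dim_; n = n_;
    for (int d = 0; d < dim; ++d) col[d] = cols[d];
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    nodes.reserve(2 * n / LEAF + 4);
    buildRec(0, n, 0);
  }

  int buildRec(int lo, int hi, int depth) {
    int id = (int)nodes.size();
    nodes.push_back(Node{lo, hi, -1, 0.0, -1, -1});
    if (hi - lo <= LEAF) return id;
    // split on dimension of largest spread
    int bd = 0; double bs = -1.0;
    for (int d = 0; d < dim; ++d) {
      double mn = col[d][idx[lo]], mx = mn;
      for (int i = lo + 1; i < hi; ++i) {
        double v = col[d][idx[i]];
        if (v < mn) mn = v; else if (v > mx) mx = v;
      }
      if (mx - mn > bs) { bs = mx - mn; bd = d; }
    }
    int mid = (lo + hi) / 2;
    const double* c = col[bd];
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [c](int a, int b) { return c[a] < c[b]; });
    nodes[id].d = bd;
    nodes[id].v = c[idx[mid]];
    int L = buildRec(lo, mid, depth + 1);
    int R = buildRec(mid, hi, depth + 1);
    nodes[id].left = L; nodes[id].right = R;
    return id;
  }

  inline double ptdist(int j, const double* q) const {
    double m = 0.0;
    for (int d = 0; d < dim; ++d) {
      double a = std::fabs(col[d][j] - q[d]);
      if (a > m) m = a;
    }
    return m;
  }

  // distance to k-th nearest neighbor of point `self` (excluded), max-norm
  double knnDist(const double* q, int self, int k) const {
    std::vector<double> heap;   // max-heap of current k best
    heap.reserve(k + 1);
    knnRec(0, q, self, k, heap);
    return heap.front();
  }

  void knnRec(int node, const double* q, int self, int k,
              std::vector<double>& heap) const {
    const Node& nd = nodes[node];
    if (nd.d < 0) {  // leaf
      for (int i = nd.lo; i < nd.hi; ++i) {
        int j = idx[i];
        if (j == self) continue;
        double dist = ptdist(j, q);
        if ((int)heap.size() < k) {
          heap.push_back(dist);
          std::push_heap(heap.begin(), heap.end());
        } else if (dist < heap.front()) {
          std::pop_heap(heap.begin(), heap.end());
          heap.back() = dist;
          std::push_heap(heap.begin(), heap.end());
        }
      }
      return;
    }
    double delta = q[nd.d] - nd.v;
    int near = delta < 0 ? nd.left : nd.right;
    int far  = delta < 0 ? nd.right : nd.left;
    knnRec(near, q, self, k, heap);
    if ((int)heap.size() < k || std::fabs(delta) < heap.front())
      knnRec(far, q, self, k, heap);
  }

  // count points with max-norm distance strictly < eps, excluding `self`
  int countWithin(const double* q, int self, double eps) const {
    return countRec(0, q, self, eps);
  }

  int countRec(int node, const double* q, int self, double eps) const {
    const Node& nd = nodes[node];
    if (nd.d < 0) {
      int c = 0;
      for (int i = nd.lo; i < nd.hi; ++i) {
        int j = idx[i];
        if (j == self) continue;
        if (ptdist(j, q) < eps) ++c;
      }
      return c;
    }
    double delta = q[nd.d] - nd.v;
    int c = 0;
    if (delta < 0) {
      c += countRec(nd.left, q, self, eps);
      if (-delta < eps) c += countRec(nd.right, q, self, eps);
    } else {
      c += countRec(nd.right, q, self, eps);
      if (delta < eps) c += countRec(nd.left, q, self, eps);
    }
    return c;
  }
};

// strict count of sorted values with |s - v| < eps, minus one for the point
// itself; binary search gives the approximate range, boundaries are then
// trimmed with the exact |s - v| < eps comparison (v +- eps rounds, which
// would miscount points whose k-th-neighbor distance is realized on this axis)
inline int count1d(const std::vector<double>& s, double v, double eps) {
  int n = (int)s.size();
  int lo = (int)(std::lower_bound(s.begin(), s.end(), v - eps) - s.begin());
  int hi = (int)(std::lower_bound(s.begin(), s.end(), v + eps) - s.begin());
  while (lo > 0 && std::fabs(s[lo - 1] - v) < eps) --lo;
  while (lo < hi && !(std::fabs(s[lo] - v) < eps)) ++lo;
  while (hi < n && std::fabs(s[hi] - v) < eps) ++hi;
  while (hi > lo && !(std::fabs(s[hi - 1] - v) < eps)) --hi;
  return hi - lo - 1;
}

}  // namespace

// [[Rcpp::export]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (k < 1) stop("k must be >= 1");
  if (n < k + 2) stop("need at least k + 2 samples");

  const double* cols[2] = {REAL(x), REAL(y)};
  KdTree tree;
  tree.build(cols, 2, n);

  std::vector<double> xs(REAL(x), REAL(x) + n), ys(REAL(y), REAL(y) + n);
  std::sort(xs.begin(), xs.end());
  std::sort(ys.begin(), ys.end());

  double acc = 0.0;
  double q[2];
  for (int i = 0; i < n; ++i) {
    q[0] = x[i]; q[1] = y[i];
    double eps = tree.knnDist(q, i, k);
    int nx = count1d(xs, x[i], eps);
    int ny = count1d(ys, y[i], eps);
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)n) + R::digamma((double)k) - acc / n;
}

// Transfer entropy driver -> target: points (xf, x, y) with xf = x shifted
// tau ahead; returns psi(k) + < psi(nX+1) - psi(nXY+1) - psi(nXXf+1) >.
// [[Rcpp::export]]
double ksg_te_cpp(NumericVector xf, NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (xf.size() != n || y.size() != n) stop("coordinate lengths differ");
  if (k < 1) stop("k must be >= 1");
  if (n < k + 2) stop("need at least k + 2 samples");

  const double* cols3[3] = {REAL(xf), REAL(x), REAL(y)};
  KdTree joint;
  joint.build(cols3, 3, n);

  const double* colXY[2] = {REAL(x), REAL(y)};
  KdTree planeXY;
  planeXY.build(colXY, 2, n);

  const double* colXXf[2] = {REAL(xf), REAL(x)};
  KdTree planeXXf;
  planeXXf.build(colXXf, 2, n);

  std::vector<double> xs(REAL(x), REAL(x) + n);
  std::sort(xs.begin(), xs.end());

  double acc = 0.0;
  double q3[3], q2[2];
  for (int i = 0; i < n; ++i) {
    q3[0] = xf[i]; q3[1] = x[i]; q3[2] = y[i];
    double eps = joint.knnDist(q3, i, k);
    int nx = count1d(xs, x[i], eps);
    q2[0] = x[i]; q2[1] = y[i];
    int nxy = planeXY.countWithin(q2, i, eps);
    q2[0] = xf[i]; q2[1] = x[i];
    int nxxf = planeXXf.countWithin(q2, i, eps);
    acc += R::digamma(nx + 1.0) - R::digamma(nxy + 1.0)
         - R::digamma(nxxf + 1.0);
  }
  return R::digamma((double)k) + acc / n;
}
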