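// Bounding-volume-hierarchy accelerated point-to-triangle-mesh queries.
// The closest-point primitive follows Ericson's region decomposition; the
// BVH is a longest-axis median-split AABB tree over triangle centroids.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Node {
  double lo[3], hi[3];
  int left, right;   // -1 for leaf
  int start, count;  // range into tri order (leaf only)
};

struct TriIndex {
  // triangle corner coordinates, flat (one entry per triangle)
  std::vector<double> ax, ay, az, bx, by, bz, cx, cy, cz;
  std::vector<int> order;  // triangle ids in BVH order
  std::vector<Node> nodes;
  int ntri;

  int build(int start, int count) {
    Node nd;
    for (int k = 0; k < 3; ++k) {
      nd.lo[k] = std::numeric_limits<double>::infinity();
      nd.hi[k] = -std::numeric_limits<double>::infinity();
    }
    for (int i = start; i < start + count; ++i) {
      int t = order[i];
      const double xs[3] = {ax[t], bx[t], cx[t]};
      const double ys[3] = {ay[t], by[t], cy[t]};
      const double zs[3] = {az[t], bz[t], cz[t]};
      for (int j = 0; j < 3; ++j) {
        nd.lo[0] = std::min(nd.lo[0], xs[j]); nd.hi[0] = std::max(nd.hi[0], xs[j]);
        nd.lo[1] = std::min(nd.lo[1], ys[j]); nd.hi[1] = std::max(nd.hi[1], ys[j]);
        nd.lo[2] = std::min(nd.lo[2], zs[j]); nd.hi[2] = std::max(nd.hi[2], zs[j]);
      }
    }
    int self = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 4) {
      nodes[self].left = nodes[self].right = -1;
      nodes[self].start = start;
      nodes[self].count = count;
      return self;
    }
    // split on longest axis of the centroid bounds at the median
    double clo[3] = {1e300, 1e300, 1e300}, chi[3] = {-1e300, -1e300, -1e300};
    for (int i = start; i < start + count; ++i) {
      int t = order[i];
      double c[3] = {(ax[t] + bx[t] + cx[t]) / 3.0,
                     (ay[t] + by[t] + cy[t]) / 3.0,
                     (az[t] + bz[t] + cz[t]) / 3.0};
      for (int k = 0; k < 3; ++k) {
        clo[k] = std::min(clo[k], c[k]);
        chi[k] = std::max(chi[k], c[k]);
      }
    }
    int axis = 0;
    double span = chi[0] - clo[0];
    for (int k = 1; k < 3; ++k)
      if (chi[k] - clo[k] > span) { span = chi[k] - clo[k]; axis = k; }
    int mid = start + count / 2;
    const std::vector<double>* cxv;
    const std::vector<double>* cyv;
    const std::vector<double>* czv;
    cxv = &ax; cyv = &bx; czv = &cx;  // reused below via lambda instead
    (void)cxv; (void)cyv; (void)czv;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count,
                     [&](int p, int q) {
                       double cp, cq;
                       if (axis == 0) { cp = ax[p] + bx[p] + cx[p]; cq = ax[q] + bx[q] + cx[q]; }
                       else if (axis == 1) { cp = ay[p] + by[p] + cy[p]; cq = ay[q] + by[q] + cy[q]; }
                       else { cp = az[p] + bz[p] + cz[p]; cq = az[q] + bz[q] + cz[q]; }
                       if (cp != cq) return cp < cq;
                       return p < q;  // deterministic tie-break
                     });
    if (span <= 0.0) {  // all centroids identical: force leaf
      nodes[self].left = nodes[self].right = -1;
      nodes[self].start = start;
      nodes[self].count = count;
      return self;
    }
    int l = build(start, mid - start);
    int r = build(mid, start + count - mid);
    nodes[self].left = l;
    nodes[self].right = r;
    nodes[self].start = start;
    nodes[self].count = count;
    return self;
  }
};

inline double box_dist2(const Node& nd, const double p[3]) {
  double d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = 0.0;
    if (p[k] < nd.lo[k]) d = nd.lo[k] - p[k];
    else if (p[k] > nd.hi[k]) d = p[k] - nd.hi[k];
    d2 += d * d;
  }
  return d2;
}

// Ericson: closest point on triangle abc to p; fills out[3] and bary[3].
inline void closest_pt_tri(const double p[3], const double a[3],
                           const double b[3], const double c[3],
                           double out[3], double bary[3]) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    bary[0] = 1; bary[1] = 0; bary[2] = 0;
    return;
  }
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    bary[0] = 0; bary[1] = 1; bary[2] = 0;
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0;
    return;
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    bary[0] = 0; bary[1] = 0; bary[2] = 1;
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w;
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w;
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
}

}  // namespace

// [[Rcpp::export]]
SEXP tri_index_build(NumericMatrix V, IntegerMatrix F) {
  if (F.nrow() < 1) stop("mesh has no faces");
  TriIndex* ti = new TriIndex();
  int n = F.nrow();
  ti->ntri = n;
  ti->ax.resize(n); ti->ay.resize(n); ti->az.resize(n);
  ti->bx.resize(n); ti->by.resize(n); ti->bz.resize(n);
  ti->cx.resize(n); ti->cy.resize(n); ti->cz.resize(n);
  ti->order.resize(n);
  for (int i = 0; i < n; ++i) {
    int ia = F(i, 0) - 1, ib = F(i, 1) - 1, ic = F(i, 2) - 1;
    ti->ax[i] = V(ia, 0); ti->ay[i] = V(ia, 1); ti->az[i] = V(ia, 2);
    ti->bx[i] = V(ib, 0); ti->by[i] = V(ib, 1); ti->bz[i] = V(ib, 2);
    ti->cx[i] = V(ic, 0); ti->cy[i] = V(ic, 1); ti->cz[i] = V(ic, 2);
    ti->order[i] = i;
  }
  ti->nodes.reserve(2 * n / 4 + 2);
  ti->build(0, n);
  XPtr<TriIndex> ptr(ti, true);
  return ptr;
}

// [[Rcpp::export]]
List tri_index_query(SEXP ptrsexp, NumericMatrix Q) {
  XPtr<TriIndex> ti(ptrsexp);
  int nq = Q.nrow();
  NumericVector dist(nq);
  NumericMatrix pt(nq, 3);
  IntegerVector face(nq);
  NumericMatrix bary(nq, 3);

  std::vector<int> stack;
  stack.reserve(128);
  for (int qi = 0; qi < nq; ++qi) {
    double p[3] = {Q(qi, 0), Q(qi, 1), Q(qi, 2)};
    double best = std::numeric_limits<double>::infinity();
    double bpt[3] = {0, 0, 0}, bb[3] = {0, 0, 0};
    int bface = -1;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back();
      stack.pop_back();
      const Node& nd = ti->nodes[ni];
      if (box_dist2(nd, p) >= best) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          int t = ti->order[i];
          double a[3] = {ti->ax[t], ti->ay[t], ti->az[t]};
          double b[3] = {ti->bx[t], ti->by[t], ti->bz[t]};
          double c[3] = {ti->cx[t], ti->cy[t], ti->cz[t]};
          double out[3], bc[3];
          closest_pt_tri(p, a, b, c, out, bc);
          double d2 = 0;
          for (int k = 0; k < 3; ++k) {
            double d = p[k] - out[k];
            d2 += d * d;
          }
          if (d2 < best) {
            best = d2;
            for (int k = 0; k < 3; ++k) { bpt[k] = out[k]; bb[k] = bc[k]; }
            bface = t;
          }
        }
      } else {
        // visit nearer child first (push farther first)
        double dl = box_dist2(ti->nodes[nd.left], p);
        double dr = box_dist2(ti->nodes[nd.right], p);
        if (dl < dr) {
          stack.push_back(nd.right);
          stack.push_back(nd.left);
        } else {
          stack.push_back(nd.left);
          stack.push_back(nd.right);
        }
      }
    }
    dist[qi] = std::sqrt(best);
    pt(qi, 0) = bpt[0]; pt(qi, 1) = bpt[1]; pt(qi, 2) = bpt[2];
    face[qi] = bface + 1;
    bary(qi, 0) = bb[0]; bary(qi, 1) = bb[1]; bary(qi, 2) = bb[2];
  }
  return List::create(_["distance"] = dist, _["point"] = pt,
                      _["face"] = face, _["bary"] = bary);
}
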