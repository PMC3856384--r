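// Low-level 3D image primitives.
//
// All arrays are column-major double/int/logical vectors with a dim
// attribute handled on the R side; only the raw extents are passed here.
// Connectivity is 6 (faces) throughout, matching the package contract.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const double BIG = 1e30;
// Parabola heights for "no feature"; must stay well below BIG so that the
// lower-envelope intersections in dt1d never cross the z sentinels.
const double BIGF = 1e20;

struct Grid {
  int n1, n2, n3;
  R_xlen_t total;
  Grid(IntegerVector d) : n1(d[0]), n2(d[1]), n3(d[2]) {
    total = (R_xlen_t)n1 * n2 * n3;
  }
  inline R_xlen_t idx(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
  }
};

// Sliding min/max over [i-r, i+r] along one line, truncated at the ends.
void line_minmax(const double* in, double* out, int n, R_xlen_t stride,
                 int r, bool do_max) {
  std::deque<int> dq;
  int added = -1;
  for (int i = 0; i < n; ++i) {
    int hi = i + r;
    if (hi > n - 1) hi = n - 1;
    while (added < hi) {
      ++added;
      double v = in[(R_xlen_t)added * stride];
      while (!dq.empty()) {
        double b = in[(R_xlen_t)dq.back() * stride];
        if ((do_max && b <= v) || (!do_max && b >= v)) dq.pop_back();
        else break;
      }
      dq.push_back(added);
    }
    while (dq.front() < i - r) dq.pop_front();
    out[(R_xlen_t)i * stride] = in[(R_xlen_t)dq.front() * stride];
  }
}

// Running sum over [i-r, i+r], truncated.
void line_boxsum(const double* in, double* out, int n, R_xlen_t stride, int r) {
  std::vector<double> pre(n + 1, 0.0);
  for (int i = 0; i < n; ++i) pre[i + 1] = pre[i] + in[(R_xlen_t)i * stride];
  for (int i = 0; i < n; ++i) {
    int lo = i - r; if (lo < 0) lo = 0;
    int hi = i + r + 1; if (hi > n) hi = n;
    out[(R_xlen_t)i * stride] = pre[hi] - pre[lo];
  }
}

typedef void (*LinePass)(const double*, double*, int, R_xlen_t, int, bool);

// Apply a 1D pass along each line of the given axis (0, 1, 2).
template <typename F>
void axis_apply(double* data, const Grid& g, int axis, F fun) {
  int n = (axis == 0) ? g.n1 : (axis == 1) ? g.n2 : g.n3;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? g.n1 : (R_xlen_t)g.n1 * g.n2;
  int na = (axis == 0) ? g.n2 : g.n1;
  int nb = (axis == 2) ? g.n2 : g.n3;
  R_xlen_t sa = (axis == 0) ? (R_xlen_t)g.n1 : 1;
  R_xlen_t sb = (axis == 2) ? (R_xlen_t)g.n1 : (R_xlen_t)g.n1 * g.n2;
  std::vector<double> buf(n);
  for (int b = 0; b < nb; ++b)
    for (int a = 0; a < na; ++a) {
      double* base = data + a * sa + b * sb;
      fun(base, n, stride, buf.data());
    }
}

// 1D squared distance transform (lower envelope of parabolas), spacing h.
void dt1d(double* f, int n, double h2, int* v, double* z, double* d) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double fq = f[q] + h2 * q * q;
    double s;
    while (true) {
      int vk = v[k];
      s = (fq - (f[vk] + h2 * vk * vk)) / (2.0 * h2 * (q - vk));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = h2 * dq * dq + f[v[k]];
  }
}

}  // namespace

// Separable box min (erosion) / max (dilation) filter; rad = half-widths in
// voxels per axis; windows truncated at the grid border (outside ignored,
// i.e. treated as +/- infinity as appropriate for the adjunction).
// [[Rcpp::export(name = ".cpp_box_minmax")]]
NumericVector cpp_box_minmax(NumericVector img, IntegerVector dims,
                             IntegerVector rad, bool do_max) {
  Grid g(dims);
  NumericVector out = clone(img);
  int nmax = std::max(dims[0], std::max(dims[1], dims[2]));
  std::vector<double> res(nmax);
  for (int axis = 0; axis < 3; ++axis) {
    int r = rad[axis];
    if (r <= 0) continue;
    axis_apply(out.begin(), g, axis,
               [r, do_max, &res](double* base, int n, R_xlen_t stride,
                                 double* buf) {
                 for (int i = 0; i < n; ++i) buf[i] = base[(R_xlen_t)i * stride];
                 line_minmax(buf, res.data(), n, 1, r, do_max);
                 for (int i = 0; i < n; ++i)
                   base[(R_xlen_t)i * stride] = res[i];
               });
  }
  return out;
}

// Separable truncated box sum; rad = half-widths in voxels.
// [[Rcpp::export(name = ".cpp_boxsum")]]
NumericVector cpp_boxsum(NumericVector img, IntegerVector dims,
                         IntegerVector rad) {
  Grid g(dims);
  NumericVector out = clone(img);
  for (int axis = 0; axis < 3; ++axis) {
    int r = rad[axis];
    if (r < 0) r = 0;
    axis_apply(out.begin(), g, axis,
               [r](double* base, int n, R_xlen_t stride, double* buf) {
                 for (int i = 0; i < n; ++i) buf[i] = base[(R_xlen_t)i * stride];
                 line_boxsum(buf, buf, n, 1, r);
                 for (int i = 0; i < n; ++i) base[(R_xlen_t)i * stride] = buf[i];
               });
  }
  return out;
}

// Squared Euclidean distance (mm^2) to the nearest TRUE voxel, with
// anisotropic spacing.  All-FALSE input yields a large sentinel everywhere.
// [[Rcpp::export(name = ".cpp_sq_edt")]]
NumericVector cpp_sq_edt(LogicalVector feature, IntegerVector dims,
                         NumericVector spacing) {
  Grid g(dims);
  NumericVector out(g.total);
  for (R_xlen_t i = 0; i < g.total; ++i) out[i] = feature[i] ? 0.0 : BIGF;
  int nmax = std::max(g.n1, std::max(g.n2, g.n3));
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1), d(nmax), f(nmax);
  for (int axis = 0; axis < 3; ++axis) {
    double h2 = spacing[axis] * spacing[axis];
    axis_apply(out.begin(), g, axis,
               [&, h2](double* base, int n, R_xlen_t stride, double* buf) {
                 for (int i = 0; i < n; ++i) f[i] = base[(R_xlen_t)i * stride];
                 dt1d(f.data(), n, h2, v.data(), z.data(), d.data());
                 for (int i = 0; i < n; ++i) base[(R_xlen_t)i * stride] = d[i];
               });
  }
  return out;
}

// Separable Gaussian smoothing, sigma per axis in voxels; the kernel is
// truncated at 3.5 sigma and renormalized where it overlaps the border.
// [[Rcpp::export(name = ".cpp_gauss")]]
NumericVector cpp_gauss(NumericVector img, IntegerVector dims,
                        NumericVector sigma_vox) {
  Grid g(dims);
  NumericVector out = clone(img);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int R = (int)std::ceil(3.5 * s);
    std::vector<double> w(2 * R + 1);
    for (int k = -R; k <= R; ++k)
      w[k + R] = std::exp(-0.5 * (k / s) * (k / s));
    axis_apply(out.begin(), g, axis,
               [&](double* base, int n, R_xlen_t stride, double* buf) {
                 for (int i = 0; i < n; ++i) buf[i] = base[(R_xlen_t)i * stride];
                 for (int i = 0; i < n; ++i) {
                   double acc = 0.0, norm = 0.0;
                   int lo = std::max(-R, -i), hi = std::min(R, n - 1 - i);
                   for (int k = lo; k <= hi; ++k) {
                     acc += w[k + R] * buf[i + k];
                     norm += w[k + R];
                   }
                   base[(R_xlen_t)i * stride] = acc / norm;
                 }
               });
  }
  return out;
}

// Min/max over an explicit voxel-offset footprint; out-of-grid offsets are
// skipped.  If a mask is supplied, only in-mask voxels contribute and
// out-of-mask centres produce 0.
// [[Rcpp::export(name = ".cpp_footprint_minmax")]]
NumericVector cpp_footprint_minmax(NumericVector img, IntegerVector dims,
                                   IntegerMatrix offs, bool do_max,
                                   Nullable<LogicalVector> mask_) {
  Grid g(dims);
  NumericVector out(g.total);
  int m = offs.nrow();
  bool masked = mask_.isNotNull();
  LogicalVector mask;
  if (masked) mask = mask_.get();
  for (int k = 0; k < g.n3; ++k)
    for (int j = 0; j < g.n2; ++j)
      for (int i = 0; i < g.n1; ++i) {
        R_xlen_t c = g.idx(i, j, k);
        if (masked && !mask[c]) { out[c] = 0.0; continue; }
        double best = do_max ? -BIG : BIG;
        bool any = false;
        for (int o = 0; o < m; ++o) {
          int ii = i + offs(o, 0), jj = j + offs(o, 1), kk = k + offs(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= g.n1 || jj >= g.n2 ||
              kk >= g.n3)
            continue;
          R_xlen_t q = g.idx(ii, jj, kk);
          if (masked && !mask[q]) continue;
          double v = img[q];
          if (do_max ? (v > best) : (v < best)) best = v;
          any = true;
        }
        out[c] = any ? best : img[c];
      }
  return out;
}

// 6-connected component labelling; labels assigned in column-major scan
// order of each component's first-encountered voxel (so the lowest label id
// is the first component met in scan order).
// [[Rcpp::export(name = ".cpp_label6")]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  IntegerVector lab(g.total);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const int d1[6] = {-1, 1, 0, 0, 0, 0};
  const int d2[6] = {0, 0, -1, 1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, -1, 1};
  for (int k = 0; k < g.n3; ++k)
    for (int j = 0; j < g.n2; ++j)
      for (int i = 0; i < g.n1; ++i) {
        R_xlen_t c = g.idx(i, j, k);
        if (!mask[c] || lab[c]) continue;
        ++next;
        lab[c] = next;
        stack.push_back(c);
        while (!stack.empty()) {
          R_xlen_t p = stack.back();
          stack.pop_back();
          int pk = (int)(p / ((R_xlen_t)g.n1 * g.n2));
          int rem = (int)(p % ((R_xlen_t)g.n1 * g.n2));
          int pj = rem / g.n1, pi = rem % g.n1;
          for (int o = 0; o < 6; ++o) {
            int ii = pi + d1[o], jj = pj + d2[o], kk = pk + d3[o];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= g.n1 || jj >= g.n2 ||
                kk >= g.n3)
              continue;
            R_xlen_t q = g.idx(ii, jj, kk);
            if (mask[q] && !lab[q]) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
  return lab;
}

namespace {
// Queue entry: priority is the voxel's own control value; the payload packs
// the FIFO sequence number (high bits, so payload order == insertion order)
// above the voxel index.  Because every push of a given voxel carries the
// same priority (its own control value), the first-pushed entry always wins
// the FIFO tie; later pushes of an already-queued voxel can never change
// the result and are skipped via the `queued` flags.
struct QEntry {
  double pri;
  std::uint64_t payload;
};
struct QCmp {
  // std::priority_queue is a max-heap; invert for (priority, seq) min-heap.
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.pri != b.pri) return a.pri > b.pri;
    return a.payload > b.payload;
  }
};
}  // namespace

// Watershed transform from markers: priority-flood of the control surface,
// 6-connectivity, queue ordered by control value with FIFO tie-breaking.
// No watershed-line voxels are produced; every voxel receives the label of
// the flood that reaches it first.  Marker labels are preserved.
// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerVector cpp_watershed(NumericVector control, IntegerVector markers,
                            IntegerVector dims) {
  Grid g(dims);
  IntegerVector lab = clone(markers);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  std::uint64_t seq = 0;
  const int shift = 34;  // payload = (seq << shift) | idx; idx < 2^34
  std::vector<int> pending(g.total, 0);  // label a queued voxel will take
  const int d1[6] = {-1, 1, 0, 0, 0, 0};
  const int d2[6] = {0, 0, -1, 1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, -1, 1};
  bool anym = false;
  for (int k = 0; k < g.n3; ++k)
    for (int j = 0; j < g.n2; ++j)
      for (int i = 0; i < g.n1; ++i) {
        R_xlen_t c = g.idx(i, j, k);
        if (lab[c] <= 0) continue;
        anym = true;
        for (int o = 0; o < 6; ++o) {
          int ii = i + d1[o], jj = j + d2[o], kk = k + d3[o];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= g.n1 || jj >= g.n2 ||
              kk >= g.n3)
            continue;
          R_xlen_t q = g.idx(ii, jj, kk);
          if (lab[q] == 0 && !pending[q]) {
            pending[q] = lab[c];
            pq.push(QEntry{control[q], (seq++ << shift) |
                                           (std::uint64_t)q});
          }
        }
      }
  if (!anym) stop("watershed requires at least one marker voxel");
  const std::uint64_t idx_mask = ((std::uint64_t)1 << shift) - 1;
  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    R_xlen_t c = (R_xlen_t)(e.payload & idx_mask);
    lab[c] = pending[c];
    int pk = (int)(c / ((R_xlen_t)g.n1 * g.n2));
    int rem = (int)(c % ((R_xlen_t)g.n1 * g.n2));
    int pj = rem / g.n1, pi = rem % g.n1;
    for (int o = 0; o < 6; ++o) {
      int ii = pi + d1[o], jj = pj + d2[o], kk = pk + d3[o];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= g.n1 || jj >= g.n2 || kk >= g.n3)
        continue;
      R_xlen_t q = g.idx(ii, jj, kk);
      if (lab[q] == 0 && !pending[q]) {
        pending[q] = lab[c];
        pq.push(QEntry{control[q], (seq++ << shift) | (std::uint64_t)q});
      }
    }
  }
  return lab;
}

// Reconstruction by erosion: starting from `seed` (>= `maskimg` pointwise),
// iterate g <- max(maskimg, unit 6-neighbourhood erosion of g) to a fixed
// point.  Jacobi sweeps; intended as a reference implementation for minima
// imposition, not a production filter.
// [[Rcpp::export(name = ".cpp_reconstruct_erosion")]]
NumericVector cpp_reconstruct_erosion(NumericVector seed, NumericVector maskimg,
                                      IntegerVector dims) {
  Grid g(dims);
  NumericVector cur = clone(seed);
  NumericVector nxt(g.total);
  const int d1[6] = {-1, 1, 0, 0, 0, 0};
  const int d2[6] = {0, 0, -1, 1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, -1, 1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int k = 0; k < g.n3; ++k)
      for (int j = 0; j < g.n2; ++j)
        for (int i = 0; i < g.n1; ++i) {
          R_xlen_t c = g.idx(i, j, k);
          double v = cur[c];
          for (int o = 0; o < 6; ++o) {
            int ii = i + d1[o], jj = j + d2[o], kk = k + d3[o];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= g.n1 || jj >= g.n2 ||
                kk >= g.n3)
              continue;
            double nv = cur[g.idx(ii, jj, kk)];
            if (nv < v) v = nv;
          }
          if (v < maskimg[c]) v = maskimg[c];
          if (v != cur[c]) changed = true;
          nxt[c] = v;
        }
    std::swap(cur, nxt);
  }
  return cur;
}
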