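// Low-level 3D image primitives shared by the segmentation and tractography
// stages: separable grayscale min/max filters, cubic-window median filter,
// 26-connected component labelling, marker-controlled watershed flooding, and
// batched symmetric 3x3 eigendecomposition for structure-tensor fields.
#include <RcppArmadillo.h>
#include <queue>
#include <vector>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Grayscale min (or max) filter along one axis, replicate boundary.
// [[Rcpp::export]]
NumericVector cpp_minmax_axis(NumericVector x, IntegerVector dim, int radius,
                              int axis, bool take_max) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(x.size());
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  const int a = axis - 1;
  const int len = n[a];
  // iterate over all lines perpendicular to `axis`
  int b = (a + 1) % 3, c = (a + 2) % 3;
  for (int kc = 0; kc < n[c]; ++kc) {
    for (int kb = 0; kb < n[b]; ++kb) {
      const int base = kb * stride[b] + kc * stride[c];
      for (int i = 0; i < len; ++i) {
        const int lo = clampi(i - radius, 0, len - 1);
        const int hi = clampi(i + radius, 0, len - 1);
        double v = x[base + lo * stride[a]];
        for (int j = lo + 1; j <= hi; ++j) {
          const double u = x[base + j * stride[a]];
          if (take_max ? (u > v) : (u < v)) v = u;
        }
        out[base + i * stride[a]] = v;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Median filter over a cubic window of half-width `radius`, replicate boundary.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector x, IntegerVector dim, int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(x.size());
  std::vector<double> buf;
  const int w = 2 * radius + 1;
  buf.reserve((size_t)w * w * w);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int dk = -radius; dk <= radius; ++dk) {
          const int kk = clampi(k + dk, 0, nz - 1);
          for (int dj = -radius; dj <= radius; ++dj) {
            const int jj = clampi(j + dj, 0, ny - 1);
            for (int di = -radius; di <= radius; ++di) {
              const int ii = clampi(i + di, 0, nx - 1);
              buf.push_back(x[ii + nx * (jj + (size_t)ny * kk)]);
            }
          }
        }
        const size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double m = buf[mid];
        if (buf.size() % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + mid);
          m = 0.5 * (m + lo);
        }
        out[i + nx * (j + (size_t)ny * k)] = m;
      }
  out.attr("dim") = dim;
  return out;
}

static void neighbours26(int idx, int nx, int ny, int nz, std::vector<int> &nb) {
  nb.clear();
  const int i = idx % nx, j = (idx / nx) % ny, k = idx / (nx * ny);
  for (int dk = -1; dk <= 1; ++dk) {
    const int kk = k + dk;
    if (kk < 0 || kk >= nz) continue;
    for (int dj = -1; dj <= 1; ++dj) {
      const int jj = j + dj;
      if (jj < 0 || jj >= ny) continue;
      for (int di = -1; di <= 1; ++di) {
        const int ii = i + di;
        if (ii < 0 || ii >= nx || (di == 0 && dj == 0 && dk == 0)) continue;
        nb.push_back(ii + nx * (jj + ny * kk));
      }
    }
  }
}

// 26-connected component labelling of a logical mask; labels 1..n by first
// encountered voxel in column-major order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ntot = nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<int> stack, nb;
  nb.reserve(26);
  int next = 0;
  for (int s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      neighbours26(v, nx, ny, nz, nb);
      for (int u : nb)
        if (mask[u] && !lab[u]) {
          lab[u] = next;
          stack.push_back(u);
        }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

struct QItem {
  double val;
  long order;
  int idx;
  int label;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.val != b.val) return a.val > b.val;  // min-heap on value
    return a.order > b.order;                  // FIFO tie-break
  }
};

// Marker-controlled watershed: flood `img` (topological surface; basins are
// minima) from labelled markers, restricted to `mask`. 26-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector img, IntegerVector markers,
                              LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ntot = nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long order = 0;
  std::vector<int> nb;
  nb.reserve(26);
  for (int s = 0; s < ntot; ++s)
    if (markers[s] > 0 && mask[s]) {
      lab[s] = markers[s];
      pq.push({img[s], order++, s, markers[s]});
    }
  while (!pq.empty()) {
    const QItem it = pq.top();
    pq.pop();
    neighbours26(it.idx, nx, ny, nz, nb);
    for (int u : nb) {
      if (!mask[u] || lab[u]) continue;
      lab[u] = it.label;
      pq.push({img[u], order++, u, it.label});
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Smallest-eigenvalue eigenvector (and all eigenvalues, ascending) of n
// symmetric 3x3 matrices given by their unique components.
// [[Rcpp::export]]
List cpp_tensor_orientation(NumericVector xx, NumericVector yy, NumericVector zz,
                            NumericVector xy, NumericVector xz, NumericVector yz) {
  const R_xlen_t n = xx.size();
  NumericMatrix vec(n, 3);
  NumericMatrix val(n, 3);
  arma::mat33 S;
  arma::vec3 ev;
  arma::mat33 V;
  for (R_xlen_t i = 0; i < n; ++i) {
    S(0, 0) = xx[i]; S(1, 1) = yy[i]; S(2, 2) = zz[i];
    S(0, 1) = S(1, 0) = xy[i];
    S(0, 2) = S(2, 0) = xz[i];
    S(1, 2) = S(2, 1) = yz[i];
    arma::eig_sym(ev, V, S);  // ascending eigenvalues
    for (int c = 0; c < 3; ++c) {
      val(i, c) = ev(c);
      vec(i, c) = V(c, 0);
    }
  }
  return List::create(_["vectors"] = vec, _["values"] = val);
}
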