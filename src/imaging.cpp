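// Low-level 3D image kernels. All volumes are R arrays with dim = (d0, d1, d2),
// first dimension fastest (column-major); for image volumes the convention
// throughout the package is (z, y, x). Voxel spacing, where it matters, is
// passed per axis in the same order.

#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static IntegerVector get_dim3(const RObject& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 2) {
    IntegerVector d3 = IntegerVector::create(d[0], d[1], 1);
    return d3;
  }
  if (d.size() != 3) stop("expected a 2D or 3D array");
  return d;
}

// ---- separable Gaussian blur, reflecting boundary -------------------------

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * (double)i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// blur along one axis in place (src -> dst)
static void blur_axis(const std::vector<double>& src, std::vector<double>& dst,
                      const int d[3], int axis, double sigma) {
  std::vector<double> k = gauss_kernel(sigma);
  int r = ((int)k.size() - 1) / 2;
  long long stride[3] = {1, (long long)d[0], (long long)d[0] * d[1]};
  int n = d[axis];
  long long sa = stride[axis];
  // iterate over all lines along `axis`
  int oa1 = (axis + 1) % 3, oa2 = (axis + 2) % 3;
  for (int i2 = 0; i2 < d[oa2]; ++i2) {
    for (int i1 = 0; i1 < d[oa1]; ++i1) {
      long long base = (long long)i1 * stride[oa1] + (long long)i2 * stride[oa2];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) {
          int ii = reflect(i + j, n);
          acc += k[j + r] * src[base + (long long)ii * sa];
        }
        dst[base + (long long)i * sa] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector vol, NumericVector sigma) {
  IntegerVector dm = get_dim3(vol);
  int d[3] = {dm[0], dm[1], dm[2]};
  if (sigma.size() != 3) stop("sigma must have length 3");
  long long N = (long long)d[0] * d[1] * d[2];
  std::vector<double> a(vol.begin(), vol.end()), b(N);
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma[ax] > 0 && d[ax] > 1) {
      blur_axis(a, b, d, ax, sigma[ax]);
      a.swap(b);
    }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = vol.attr("dim");
  return out;
}

// ---- neighbor offsets ------------------------------------------------------

static void neighbor_offsets(const int d[3], int connectivity,
                             std::vector<int>& dz, std::vector<int>& dy,
                             std::vector<int>& dx) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  (void)d;
}

// ---- 3D connected components ----------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, int connectivity = 26) {
  IntegerVector dm = get_dim3(mask);
  int d[3] = {dm[0], dm[1], dm[2]};
  long long N = (long long)d[0] * d[1] * d[2];
  IntegerVector lab(N, 0);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(d, connectivity, dz, dy, dx);
  int nn = dz.size();
  int next = 0;
  std::vector<long long> stack;
  for (long long i = 0; i < N; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      long long cur = stack.back(); stack.pop_back();
      int z = cur % d[0];
      int y = (cur / d[0]) % d[1];
      int x = cur / ((long long)d[0] * d[1]);
      for (int k = 0; k < nn; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= d[0] || yy < 0 || yy >= d[1] || xx < 0 || xx >= d[2])
          continue;
        long long j = zz + (long long)d[0] * (yy + (long long)d[1] * xx);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("dim") = mask.attr("dim");
  return lab;
}

// ---- seeded watershed (priority flood, descending intensity) ---------------

// Flood from labeled seeds over `mask`, visiting voxels in order of
// decreasing intensity; FIFO on exact ties for bit-reproducible labels.
// Mask voxels unreachable from any seed remain 0.
// [[Rcpp::export]]
IntegerVector cpp_watershed_seeded(NumericVector intensity, IntegerVector seeds,
                                   LogicalVector mask, int connectivity = 26) {
  IntegerVector dm = get_dim3(intensity);
  int d[3] = {dm[0], dm[1], dm[2]};
  long long N = (long long)d[0] * d[1] * d[2];
  if (seeds.size() != N || mask.size() != N) stop("shape mismatch");
  IntegerVector lab(N, 0);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(d, connectivity, dz, dy, dx);
  int nn = dz.size();
  typedef std::tuple<double, long long, long long> Item; // (value, -counter, idx)
  std::priority_queue<Item> pq;
  long long counter = 0;
  for (long long i = 0; i < N; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push(Item(intensity[i], -(counter++), i));
    }
  }
  while (!pq.empty()) {
    long long cur = std::get<2>(pq.top());
    pq.pop();
    int z = cur % d[0];
    int y = (cur / d[0]) % d[1];
    int x = cur / ((long long)d[0] * d[1]);
    int curlab = lab[cur];
    for (int k = 0; k < nn; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= d[0] || yy < 0 || yy >= d[1] || xx < 0 || xx >= d[2])
        continue;
      long long j = zz + (long long)d[0] * (yy + (long long)d[1] * xx);
      if (mask[j] && lab[j] == 0) {
        lab[j] = curlab;
        pq.push(Item(intensity[j], -(counter++), j));
      }
    }
  }
  lab.attr("dim") = intensity.attr("dim");
  return lab;
}

// ---- anisotropic Euclidean distance transform ------------------------------

// Felzenszwalb & Huttenlocher lower-envelope 1D transform with physical
// sample spacing w; f holds squared distances, positions are i*w.
static void dt1d(std::vector<double>& f, int n, double w,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& out) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dd = xq - v[k] * w;
    out[q] = dd * dd + f[v[k]];
  }
}

// Distance (physical units) from every voxel to the nearest TRUE voxel of fg.
// All-FALSE input yields Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector fg, NumericVector spacing) {
  IntegerVector dm = get_dim3(fg);
  int d[3] = {dm[0], dm[1], dm[2]};
  if (spacing.size() != 3) stop("spacing must have length 3");
  long long N = (long long)d[0] * d[1] * d[2];
  const double INF = 1e30;
  std::vector<double> a(N);
  for (long long i = 0; i < N; ++i) a[i] = fg[i] ? 0.0 : INF;
  long long stride[3] = {1, (long long)d[0], (long long)d[0] * d[1]};
  int nmax = std::max(d[0], std::max(d[1], d[2]));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int ax = 0; ax < 3; ++ax) {
    if (d[ax] == 1) continue;
    int n = d[ax];
    double w = spacing[ax];
    long long sa = stride[ax];
    int oa1 = (ax + 1) % 3, oa2 = (ax + 2) % 3;
    for (int i2 = 0; i2 < d[oa2]; ++i2) {
      for (int i1 = 0; i1 < d[oa1]; ++i1) {
        long long base = (long long)i1 * stride[oa1] + (long long)i2 * stride[oa2];
        for (int i = 0; i < n; ++i) f[i] = a[base + (long long)i * sa];
        dt1d(f, n, w, v, z, out);
        for (int i = 0; i < n; ++i) a[base + (long long)i * sa] = out[i];
      }
    }
  }
  NumericVector res(N);
  for (long long i = 0; i < N; ++i)
    res[i] = (a[i] >= 1e29) ? R_PosInf : std::sqrt(a[i]);
  res.attr("dim") = fg.attr("dim");
  return res;
}

// ---- 3D local maxima -------------------------------------------------------

// Strict local maxima above `floor_` under 26-connectivity; on plateaus the
// voxel with the smallest linear index wins (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_local_max3(NumericVector vol, double floor_) {
  IntegerVector dm = get_dim3(vol);
  int d[3] = {dm[0], dm[1], dm[2]};
  long long N = (long long)d[0] * d[1] * d[2];
  std::vector<int> dz, dy, dx;
  neighbor_offsets(d, 26, dz, dy, dx);
  int nn = dz.size();
  std::vector<long long> hits;
  for (long long i = 0; i < N; ++i) {
    double v = vol[i];
    if (!(v > floor_)) continue;
    int z = i % d[0];
    int y = (i / d[0]) % d[1];
    int x = i / ((long long)d[0] * d[1]);
    bool ok = true;
    for (int k = 0; k < nn && ok; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= d[0] || yy < 0 || yy >= d[1] || xx < 0 || xx >= d[2])
        continue;
      long long j = zz + (long long)d[0] * (yy + (long long)d[1] * xx);
      if (vol[j] > v || (vol[j] == v && j < i)) ok = false;
    }
    if (ok) hits.push_back(i + 1); // 1-based linear index
  }
  return IntegerVector(hits.begin(), hits.end());
}
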