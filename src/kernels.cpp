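// Voxel-level kernels: resampling, smoothing, seeded segmentation,
// distance transforms, isosurfacing, and the registration metric.
// Arrays are R column-major: linear index l = i + nx*(j + ny*k), 0-based.
#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <unordered_map>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z, double outside,
                               bool* ok = nullptr) {
  if (ok) *ok = true;
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    if (ok) *ok = false;
    return outside;
  }
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  size_t b = i0 + sy * j0 + sz * k0;
  double c000 = v[b], c100 = v[b + sx], c010 = v[b + sy], c110 = v[b + sx + sy];
  double c001 = v[b + sz], c101 = v[b + sx + sz], c011 = v[b + sy + sz],
         c111 = v[b + sx + sy + sz];
  double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// A is 3x4: input continuous index = A[,1:3] %*% output index + A[,4]
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector values, IntegerVector dims_in,
                                     IntegerVector dims_out, NumericMatrix A,
                                     double outside) {
  int nxi = dims_in[0], nyi = dims_in[1], nzi = dims_in[2];
  int nxo = dims_out[0], nyo = dims_out[1], nzo = dims_out[2];
  NumericVector out((size_t)nxo * nyo * nzo);
  const double* v = values.begin();
  size_t l = 0;
  for (int k = 0; k < nzo; k++)
    for (int j = 0; j < nyo; j++)
      for (int i = 0; i < nxo; i++, l++) {
        double x = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + A(0, 3);
        double y = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + A(1, 3);
        double z = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + A(2, 3);
        out[l] = trilinear(v, nxi, nyi, nzi, x, y, z, outside);
      }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_resample_nn(IntegerVector codes, IntegerVector dims_in,
                              IntegerVector dims_out, NumericMatrix A) {
  int nxi = dims_in[0], nyi = dims_in[1], nzi = dims_in[2];
  int nxo = dims_out[0], nyo = dims_out[1], nzo = dims_out[2];
  IntegerVector out((size_t)nxo * nyo * nzo);
  size_t l = 0;
  for (int k = 0; k < nzo; k++)
    for (int j = 0; j < nyo; j++)
      for (int i = 0; i < nxo; i++, l++) {
        double x = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + A(0, 3);
        double y = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + A(1, 3);
        double z = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + A(2, 3);
        long ii = (long)std::lround(x), jj = (long)std::lround(y),
             kk = (long)std::lround(z);
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nxi || jj >= nyi || kk >= nzi)
          out[l] = 0;
        else
          out[l] = codes[(size_t)ii + (size_t)nxi * (jj + (size_t)nyi * kk)];
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector values, IntegerVector dims,
                                NumericMatrix pts) {
  // pts: N x 3 continuous 0-based index coordinates
  int n = pts.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; r++) {
    double x = pts(r, 0), y = pts(r, 1), z = pts(r, 2);
    // clamp to the domain: callers sample fields defined on the whole grid
    if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
    if (x > dims[0] - 1) x = dims[0] - 1;
    if (y > dims[1] - 1) y = dims[1] - 1;
    if (z > dims[2] - 1) z = dims[2] - 1;
    out[r] = trilinear(values.begin(), dims[0], dims[1], dims[2], x, y, z, 0.0);
  }
  return out;
}

static void blur1d(std::vector<double>& buf, std::vector<double>& tmp,
                   const std::vector<double>& kern) {
  int n = (int)buf.size(), r = ((int)kern.size() - 1) / 2;
  for (int i = 0; i < n; i++) {
    double s = 0, w = 0;
    for (int d = -r; d <= r; d++) {
      int ii = i + d;
      if (ii < 0 || ii >= n) continue;  // renormalized truncation at edges
      double kk = kern[d + r];
      s += kk * buf[ii];
      w += kk;
    }
    tmp[i] = s / w;
  }
  buf.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector values, IntegerVector dims,
                                NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(values);
  for (int ax = 0; ax < 3; ax++) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    for (int d = -r; d <= r; d++) kern[d + r] = std::exp(-0.5 * d * d / (s * s));
    int n = (ax == 0) ? nx : (ax == 1) ? ny : nz;
    std::vector<double> line(n), tmp(n);
    if (ax == 0) {
      for (int k = 0; k < nz; k++)
        for (int j = 0; j < ny; j++) {
          size_t b = (size_t)nx * (j + (size_t)ny * k);
          for (int i = 0; i < nx; i++) line[i] = out[b + i];
          blur1d(line, tmp, kern);
          for (int i = 0; i < nx; i++) out[b + i] = line[i];
        }
    } else if (ax == 1) {
      for (int k = 0; k < nz; k++)
        for (int i = 0; i < nx; i++) {
          size_t b = i + (size_t)nx * ny * k;
          for (int j = 0; j < ny; j++) line[j] = out[b + (size_t)nx * j];
          blur1d(line, tmp, kern);
          for (int j = 0; j < ny; j++) out[b + (size_t)nx * j] = line[j];
        }
    } else {
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          size_t b = i + (size_t)nx * j;
          for (int k = 0; k < nz; k++) line[k] = out[b + (size_t)nx * ny * k];
          blur1d(line, tmp, kern);
          for (int k = 0; k < nz; k++) out[b + (size_t)nx * ny * k] = line[k];
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gradient_magnitude(NumericVector values, IntegerVector dims,
                                     NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  const double* v = values.begin();
  size_t l = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, l++) {
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        double gx = (v[ip + (size_t)nx * (j + (size_t)ny * k)] -
                     v[im + (size_t)nx * (j + (size_t)ny * k)]) /
                    ((ip - im) * spacing[0]);
        double gy = (v[i + (size_t)nx * (jp + (size_t)ny * k)] -
                     v[i + (size_t)nx * (jm + (size_t)ny * k)]) /
                    ((jp - jm) * spacing[1]);
        double gz = (v[i + (size_t)nx * (j + (size_t)ny * kp)] -
                     v[i + (size_t)nx * (j + (size_t)ny * km)]) /
                    ((kp - km) * spacing[2]);
        out[l] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return out;
}

// Central-difference gradient vector; returns (gx, gy, gz) concatenated.
// [[Rcpp::export]]
NumericVector cpp_gradient_magnitude_vec(NumericVector values,
                                         IntegerVector dims,
                                         NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(3 * n);
  const double* v = values.begin();
  size_t l = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, l++) {
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        out[l] = (v[ip + (size_t)nx * (j + (size_t)ny * k)] -
                  v[im + (size_t)nx * (j + (size_t)ny * k)]) /
                 ((ip - im) * spacing[0]);
        out[n + l] = (v[i + (size_t)nx * (jp + (size_t)ny * k)] -
                      v[i + (size_t)nx * (jm + (size_t)ny * k)]) /
                     ((jp - jm) * spacing[1]);
        out[2 * n + l] = (v[i + (size_t)nx * (j + (size_t)ny * kp)] -
                          v[i + (size_t)nx * (j + (size_t)ny * km)]) /
                         ((kp - km) * spacing[2]);
      }
  return out;
}

// Competitive seeded region growing. Each seed grows its own region with
// its own running mean intensity (so one label may be represented by
// several regions, e.g. trabecular + cortical bone, or soft tissue + each
// tooth for the background). Priority = (dissimilarity to the claiming
// region's running mean, geodesic step count, label code, seed ordinal,
// voxel index): content-deterministic and, because regions are keyed by
// (code, seed position), independent of seed listing order when combined
// with the sorted-seed preprocessing on the R side.
// [[Rcpp::export]]
IntegerVector cpp_region_grow(NumericVector values, IntegerVector dims,
                              IntegerVector seed_lin, IntegerVector seed_code,
                              NumericVector fixed_means) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  int ns = seed_lin.size();
  bool frozen = fixed_means.size() == ns;
  std::vector<double> sum(ns, 0.0);
  std::vector<long> cnt(ns, 0);
  // diss, steps, code, region, lin
  typedef std::tuple<double, double, int, int, size_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  for (int s = 0; s < ns; s++) {
    pq.push(Node(0.0, 0.0, seed_code[s], s, (size_t)seed_lin[s]));
  }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    size_t l = std::get<4>(nd);
    if (lab[l] != 0) continue;
    int code = std::get<2>(nd);
    int reg = std::get<3>(nd);
    double steps = std::get<1>(nd);
    lab[l] = code;
    double mean;
    if (frozen) {
      mean = fixed_means[reg];
    } else {
      sum[reg] += values[l];
      cnt[reg] += 1;
      mean = sum[reg] / cnt[reg];
    }
    int i = (int)(l % nx), j = (int)((l / nx) % ny), k = (int)(l / ((size_t)nx * ny));
    for (int d = 0; d < 6; d++) {
      int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      size_t ln = ii + (size_t)nx * (jj + (size_t)ny * kk);
      if (lab[ln] != 0) continue;
      pq.push(Node(std::fabs(values[ln] - mean), steps + 1.0, code, reg, ln));
    }
  }
  return lab;
}

// Seeded watershed by priority flooding of a landscape (gradient magnitude),
// restricted to gated voxels (gate != 0), 6-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_watershed_flood(NumericVector landscape, IntegerVector dims,
                                  IntegerVector seed_lin, IntegerVector seed_code,
                                  IntegerVector gate) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  typedef std::tuple<double, int, size_t> Node;  // height, code, lin
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  for (int s = 0; s < seed_lin.size(); s++)
    pq.push(Node(landscape[seed_lin[s]], seed_code[s], (size_t)seed_lin[s]));
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    size_t l = std::get<2>(nd);
    if (lab[l] != 0) continue;
    int code = std::get<1>(nd);
    lab[l] = code;
    int i = (int)(l % nx), j = (int)((l / nx) % ny), k = (int)(l / ((size_t)nx * ny));
    for (int d = 0; d < 6; d++) {
      int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      size_t ln = ii + (size_t)nx * (jj + (size_t)ny * kk);
      if (lab[ln] != 0 || gate[ln] == 0) continue;
      pq.push(Node(landscape[ln], code, ln));
    }
  }
  return lab;
}

// "no site" sentinel: large but finite, so envelope arithmetic (which
// subtracts f values) never produces NaN
static const double EDT_FAR = 1e30;

// separable (box) grey-value dilation/erosion: running max/min along each
// axis with half-width r voxels per axis
static void runminmax(std::vector<double>& line, std::vector<double>& tmp,
                      int r, bool do_max) {
  int n = (int)line.size();
  for (int i = 0; i < n; i++) {
    double v = line[i];
    for (int d = -r; d <= r; d++) {
      int j = i + d;
      if (j < 0 || j >= n) continue;
      if (do_max ? line[j] > v : line[j] < v) v = line[j];
    }
    tmp[i] = v;
  }
  line.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_grey_minmax(NumericVector values, IntegerVector dims,
                              IntegerVector radius_vox, bool do_max) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(values);
  for (int ax = 0; ax < 3; ax++) {
    int r = radius_vox[ax];
    if (r <= 0) continue;
    int n = (ax == 0) ? nx : (ax == 1) ? ny : nz;
    std::vector<double> line(n), tmp(n);
    if (ax == 0) {
      for (int k = 0; k < nz; k++)
        for (int j = 0; j < ny; j++) {
          size_t b = (size_t)nx * (j + (size_t)ny * k);
          for (int i = 0; i < nx; i++) line[i] = out[b + i];
          runminmax(line, tmp, r, do_max);
          for (int i = 0; i < nx; i++) out[b + i] = line[i];
        }
    } else if (ax == 1) {
      for (int k = 0; k < nz; k++)
        for (int i = 0; i < nx; i++) {
          size_t b = i + (size_t)nx * ny * k;
          for (int j = 0; j < ny; j++) line[j] = out[b + (size_t)nx * j];
          runminmax(line, tmp, r, do_max);
          for (int j = 0; j < ny; j++) out[b + (size_t)nx * j] = line[j];
        }
    } else {
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          size_t b = i + (size_t)nx * j;
          for (int k = 0; k < nz; k++) line[k] = out[b + (size_t)nx * ny * k];
          runminmax(line, tmp, r, do_max);
          for (int k = 0; k < nz; k++) out[b + (size_t)nx * ny * k] = line[k];
        }
    }
  }
  return out;
}

static void edt1d(std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& zv, double sp) {
  int n = (int)f.size();
  double sp2 = sp * sp;
  int k = 0;
  v[0] = 0;
  zv[0] = -std::numeric_limits<double>::infinity();
  zv[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + sp2 * q * q) - (f[v[k]] + sp2 * v[k] * v[k])) /
          (2.0 * sp2 * (q - v[k]));
      if (s <= zv[k]) k--; else break;
    }
    k++;
    v[k] = q;
    zv[k] = s;
    zv[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (zv[k + 1] < q) k++;
    d[q] = sp2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
  for (int q = 0; q < n; q++) f[q] = d[q];
}

// Squared Euclidean distance (mm^2) to the nearest voxel with mask != 0.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  for (size_t l = 0; l < n; l++) out[l] = mask[l] != 0 ? 0.0 : EDT_FAR;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zv(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      size_t b = (size_t)nx * (j + (size_t)ny * k);
      f.assign(out.begin() + b, out.begin() + b + nx);
      edt1d(f, d, v, zv, spacing[0]);
      for (int i = 0; i < nx; i++) out[b + i] = f[i];
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      size_t b = i + (size_t)nx * ny * k;
      f.resize(ny);
      for (int j = 0; j < ny; j++) f[j] = out[b + (size_t)nx * j];
      edt1d(f, d, v, zv, spacing[1]);
      for (int j = 0; j < ny; j++) out[b + (size_t)nx * j] = f[j];
    }
  // z pass
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      size_t b = i + (size_t)nx * j;
      f.resize(nz);
      for (int k = 0; k < nz; k++) f[k] = out[b + (size_t)nx * ny * k];
      edt1d(f, d, v, zv, spacing[2]);
      for (int k = 0; k < nz; k++) out[b + (size_t)nx * ny * k] = f[k];
    }
  return out;
}

// [[Rcpp::export]]
List cpp_connected_components(IntegerVector mask, IntegerVector dims,
                              int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> offs;
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back(di);
        offs.push_back(dj);
        offs.push_back(dk);
      }
  int ncomp = 0;
  std::vector<size_t> stack;
  for (size_t l0 = 0; l0 < n; l0++) {
    if (mask[l0] == 0 || lab[l0] != 0) continue;
    ncomp++;
    lab[l0] = ncomp;
    stack.clear();
    stack.push_back(l0);
    while (!stack.empty()) {
      size_t l = stack.back();
      stack.pop_back();
      int i = (int)(l % nx), j = (int)((l / nx) % ny),
          k = (int)(l / ((size_t)nx * ny));
      for (size_t o = 0; o < offs.size(); o += 3) {
        int ii = i + offs[o], jj = j + offs[o + 1], kk = k + offs[o + 2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t ln = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (mask[ln] == 0 || lab[ln] != 0) continue;
        lab[ln] = ncomp;
        stack.push_back(ln);
      }
    }
  }
  return List::create(_["labels"] = lab, _["n"] = ncomp);
}

// Normalized cross-correlation between fixed voxels (optionally restricted to
// fixed_mask != 0) and the moving image resampled through the affine index
// map A (3x4, fixed index -> moving continuous index). Voxels mapping outside
// the moving domain are excluded.
// [[Rcpp::export]]
List cpp_ncc_affine(NumericVector fixed, IntegerVector dims_f,
                    IntegerVector fixed_mask, NumericVector moving,
                    IntegerVector dims_m, NumericMatrix A) {
  int nx = dims_f[0], ny = dims_f[1], nz = dims_f[2];
  bool use_mask = fixed_mask.size() > 1;
  double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  long cnt = 0;
  const double* mv = moving.begin();
  size_t l = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, l++) {
        if (use_mask && fixed_mask[l] == 0) continue;
        double x = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + A(0, 3);
        double y = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + A(1, 3);
        double z = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + A(2, 3);
        bool ok;
        double m = trilinear(mv, dims_m[0], dims_m[1], dims_m[2], x, y, z, 0, &ok);
        if (!ok) continue;
        double f = fixed[l];
        sf += f; sm += m; sff += f * f; smm += m * m; sfm += f * m;
        cnt++;
      }
  double ncc = NA_REAL;
  if (cnt > 1) {
    double varf = sff - sf * sf / cnt, varm = smm - sm * sm / cnt;
    double cov = sfm - sf * sm / cnt;
    if (varf > 0 && varm > 0) ncc = cov / std::sqrt(varf * varm);
  }
  return List::create(_["ncc"] = ncc, _["n"] = (double)cnt);
}

// Marching tetrahedra on a binary field at the 0.5 iso-level.
// Returns vertices in continuous 0-based index coordinates of the INPUT grid
// (callers pad the field; pad offset handled here via `offset`) and 1-based
// triangle indices. Triangles are oriented with outward normals.
namespace {
struct MTState {
  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};
}

static int edge_vertex(MTState& st, size_t la, size_t lb, const int* ia,
                       const int* ib) {
  uint64_t key = la < lb ? (uint64_t)la << 32 | lb : (uint64_t)lb << 32 | la;
  auto it = st.edge_vert.find(key);
  if (it != st.edge_vert.end()) return it->second;
  int id = (int)st.vx.size();
  st.vx.push_back(0.5 * (ia[0] + ib[0]));
  st.vy.push_back(0.5 * (ia[1] + ib[1]));
  st.vz.push_back(0.5 * (ia[2] + ib[2]));
  st.edge_vert[key] = id;
  return id;
}

static void emit_tri(MTState& st, int a, int b, int c, const double* inside_pt) {
  // orient so the normal points away from inside_pt
  double p0[3] = {st.vx[a], st.vy[a], st.vz[a]};
  double p1[3] = {st.vx[b], st.vy[b], st.vz[b]};
  double p2[3] = {st.vx[c], st.vy[c], st.vz[c]};
  double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double w[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
  double nvec[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                    u[0] * w[1] - u[1] * w[0]};
  double cx = (p0[0] + p1[0] + p2[0]) / 3 - inside_pt[0];
  double cy = (p0[1] + p1[1] + p2[1]) / 3 - inside_pt[1];
  double cz = (p0[2] + p1[2] + p2[2]) / 3 - inside_pt[2];
  double dot = nvec[0] * cx + nvec[1] * cy + nvec[2] * cz;
  if (dot < 0) std::swap(b, c);
  st.tri.push_back(a);
  st.tri.push_back(b);
  st.tri.push_back(c);
}

// [[Rcpp::export]]
List cpp_marching_tetra(IntegerVector mask, IntegerVector dims, double offset) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  // cube corner bit order: c = (di) | (dj<<1) | (dk<<2)
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  MTState st;
  int corner_idx[8][3];
  size_t corner_lin[8];
  for (int k = 0; k < nz - 1; k++)
    for (int j = 0; j < ny - 1; j++)
      for (int i = 0; i < nx - 1; i++) {
        int inmask = 0;
        for (int c = 0; c < 8; c++) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          corner_idx[c][0] = i + di;
          corner_idx[c][1] = j + dj;
          corner_idx[c][2] = k + dk;
          corner_lin[c] = (size_t)(i + di) +
                          (size_t)nx * ((j + dj) + (size_t)ny * (k + dk));
          if (mask[corner_lin[c]] != 0) inmask |= (1 << c);
        }
        if (inmask == 0 || inmask == 255) continue;
        for (int t = 0; t < 6; t++) {
          int vc[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], nin = 0;
          for (int q = 0; q < 4; q++) in[q] = (inmask >> vc[q]) & 1, nin += in[q];
          if (nin == 0 || nin == 4) continue;
          // centroid of inside corners = reference interior point
          double ip[3] = {0, 0, 0};
          int cntin = 0;
          for (int q = 0; q < 4; q++)
            if (in[q]) {
              ip[0] += corner_idx[vc[q]][0];
              ip[1] += corner_idx[vc[q]][1];
              ip[2] += corner_idx[vc[q]][2];
              cntin++;
            }
          ip[0] /= cntin; ip[1] /= cntin; ip[2] /= cntin;
          int inq[3], outq[3], ni = 0, no = 0;
          for (int q = 0; q < 4; q++) (in[q] ? inq[ni++] : outq[no++]) = vc[q];
          if (nin == 1) {
            int a = edge_vertex(st, corner_lin[inq[0]], corner_lin[outq[0]],
                                corner_idx[inq[0]], corner_idx[outq[0]]);
            int b = edge_vertex(st, corner_lin[inq[0]], corner_lin[outq[1]],
                                corner_idx[inq[0]], corner_idx[outq[1]]);
            int c = edge_vertex(st, corner_lin[inq[0]], corner_lin[outq[2]],
                                corner_idx[inq[0]], corner_idx[outq[2]]);
            emit_tri(st, a, b, c, ip);
          } else if (nin == 3) {
            int a = edge_vertex(st, corner_lin[inq[0]], corner_lin[outq[0]],
                                corner_idx[inq[0]], corner_idx[outq[0]]);
            int b = edge_vertex(st, corner_lin[inq[1]], corner_lin[outq[0]],
                                corner_idx[inq[1]], corner_idx[outq[0]]);
            int c = edge_vertex(st, corner_lin[inq[2]], corner_lin[outq[0]],
                                corner_idx[inq[2]], corner_idx[outq[0]]);
            emit_tri(st, a, b, c, ip);
          } else {  // 2 in, 2 out -> quad split into two triangles
            int a = edge_vertex(st, corner_lin[inq[0]], corner_lin[outq[0]],
                                corner_idx[inq[0]], corner_idx[outq[0]]);
            int b = edge_vertex(st, corner_lin[inq[0]], corner_lin[outq[1]],
                                corner_idx[inq[0]], corner_idx[outq[1]]);
            int c = edge_vertex(st, corner_lin[inq[1]], corner_lin[outq[1]],
                                corner_idx[inq[1]], corner_idx[outq[1]]);
            int d = edge_vertex(st, corner_lin[inq[1]], corner_lin[outq[0]],
                                corner_idx[inq[1]], corner_idx[outq[0]]);
            emit_tri(st, a, b, c, ip);
            emit_tri(st, a, c, d, ip);
          }
        }
      }
  int nv = (int)st.vx.size(), nt = (int)st.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int r = 0; r < nv; r++) {
    V(r, 0) = st.vx[r] + offset;
    V(r, 1) = st.vy[r] + offset;
    V(r, 2) = st.vz[r] + offset;
  }
  IntegerMatrix T(nt, 3);
  for (int r = 0; r < nt; r++) {
    T(r, 0) = st.tri[3 * r] + 1;
    T(r, 1) = st.tri[3 * r + 1] + 1;
    T(r, 2) = st.tri[3 * r + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}
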