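#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e20;

// Lower-envelope 1D squared distance transform (Felzenszwalb & Huttenlocher).
// f holds squared distances from the previous pass; d receives the result.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
      if (s <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Variant evaluating the lower envelope at q + 0.5 (half-voxel-offset query
// points) while the parabolas stay anchored at integer sites.
static void dt1d_half(const std::vector<double> &f, std::vector<double> &d,
                      int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
      if (s <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q + 0.5;
    while (z[k + 1] < qq) ++k;
    double dq = qq - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance from every foreground voxel to the nearest
// background voxel center. Array is column-major with dims (n1, n2, n3).
// border_bg treats the half-spaces outside the grid as background, so a
// foreground voxel on the grid face is at distance 1 from the virtual layer
// of centers just outside. offset_axis in {0,1,2} evaluates the transform at
// points shifted by +0.5 voxel along that axis (the midpoints toward the
// next voxel); -1 evaluates at the voxel centers.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector fg, IntegerVector dims, bool border_bg,
                         int offset_axis = -1) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  if (fg.size() != N) stop("mask size does not match dims");
  std::vector<double> D((size_t)N);
  for (R_xlen_t i = 0; i < N; ++i) D[i] = fg[i] ? BIG : 0.0;

  int ns[3] = {n1, n2, n3};
  R_xlen_t strides[3] = {1, n1, (R_xlen_t)n1 * n2};
  int pad = border_bg ? 1 : 0;

  // process the offset axis last so every other pass is a plain transform
  int order[3] = {0, 1, 2};
  if (offset_axis >= 0) {
    int k = 0;
    for (int ax = 0; ax < 3; ++ax) if (ax != offset_axis) order[k++] = ax;
    order[2] = offset_axis;
  }
  for (int oi = 0; oi < 3; ++oi) {
    int ax = order[oi];
    bool half = (ax == offset_axis);
    int L = ns[ax];
    if (L == 1) continue;  // singleton axis: the volume is effectively 2D
    int Lp = L + 2 * pad;
    std::vector<double> f(Lp), d(Lp);
    int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
    for (int b = 0; b < ns[ob]; ++b) {
      for (int a = 0; a < ns[oa]; ++a) {
        R_xlen_t base = (R_xlen_t)a * strides[oa] + (R_xlen_t)b * strides[ob];
        if (pad) { f[0] = 0.0; f[Lp - 1] = 0.0; }
        for (int q = 0; q < L; ++q) f[q + pad] = D[base + (R_xlen_t)q * strides[ax]];
        if (half) dt1d_half(f, d, Lp); else dt1d(f, d, Lp);
        for (int q = 0; q < L; ++q) D[base + (R_xlen_t)q * strides[ax]] = d[q + pad];
      }
    }
  }
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = (D[i] >= BIG) ? R_PosInf : D[i];
  return out;
}

struct Center {
  double x, y, z;
  double rho;
};

// Maximal-inscribed-sphere local thickness. For each pore voxel, the diameter
// (2 * rho, voxel units) of the largest ball that covers the voxel, over
// candidate centers at every pore voxel (effective radius
// rho = sqrt(edt_sq) - 0.5) and, when the offset transforms are supplied, at
// the midpoints between axis-adjacent pore-voxel pairs — without the
// midpoints an even-width gap measures one voxel low, because its true
// maximal ball sits between voxel centers. Voxel centers whose ball is
// contained in a 26-neighbor's ball are skipped (distance-ridge reduction);
// containment ball(c,rc) <= ball(d,rd) iff rd >= rc + |cd|.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(NumericVector edt_sq, LogicalVector pore,
                                  IntegerVector dims,
                                  Nullable<NumericVector> edt_half1 = R_NilValue,
                                  Nullable<NumericVector> edt_half2 = R_NilValue,
                                  Nullable<NumericVector> edt_half3 = R_NilValue) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  if (edt_sq.size() != N || pore.size() != N) stop("size mismatch");
  NumericVector th(N, 0.0);

  std::vector<Center> centers;      // voxel-center candidates
  std::vector<R_xlen_t> center_idx;
  centers.reserve((size_t)N / 4);
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        R_xlen_t i = x + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * z);
        if (!pore[i]) continue;
        double r = std::sqrt(edt_sq[i]) - 0.5;
        if (r < 0) r = 0;
        centers.push_back({(double)x, (double)y, (double)z, r});
        center_idx.push_back(i);
      }
  if (centers.empty()) return th;

  // rho lookup for the neighbor test
  std::vector<double> rho((size_t)N, -1.0);
  for (size_t k = 0; k < centers.size(); ++k) rho[center_idx[k]] = centers[k].rho;

  std::vector<Center> kept;
  kept.reserve(centers.size());
  for (const Center &c : centers) {
    bool dominated = false;
    int cx = (int)c.x, cy = (int)c.y, cz = (int)c.z;
    for (int dz = -1; dz <= 1 && !dominated; ++dz)
      for (int dy = -1; dy <= 1 && !dominated; ++dy)
        for (int dx = -1; dx <= 1 && !dominated; ++dx) {
          if (!dx && !dy && !dz) continue;
          int x = cx + dx, y = cy + dy, z = cz + dz;
          if (x < 0 || y < 0 || z < 0 || x >= n1 || y >= n2 || z >= n3) continue;
          R_xlen_t j = x + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * z);
          if (rho[j] < 0) continue;
          double dist = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
          if (rho[j] >= c.rho + dist - 1e-12) dominated = true;
        }
    if (!dominated) kept.push_back(c);
  }

  // midpoint candidates between axis-adjacent pore voxels, skipped when an
  // endpoint ball already contains them
  const NumericVector *halves[3] = {nullptr, nullptr, nullptr};
  NumericVector h1, h2, h3;
  if (edt_half1.isNotNull()) { h1 = edt_half1.get(); if (h1.size() == N) halves[0] = &h1; }
  if (edt_half2.isNotNull()) { h2 = edt_half2.get(); if (h2.size() == N) halves[1] = &h2; }
  if (edt_half3.isNotNull()) { h3 = edt_half3.get(); if (h3.size() == N) halves[2] = &h3; }
  for (int ax = 0; ax < 3; ++ax) {
    if (!halves[ax]) continue;
    const NumericVector &hv = *halves[ax];
    R_xlen_t stride = (ax == 0) ? 1 : (ax == 1 ? n1 : (R_xlen_t)n1 * n2);
    int ext = (ax == 0) ? n1 : (ax == 1 ? n2 : n3);
    for (size_t k = 0; k < centers.size(); ++k) {
      const Center &c = centers[k];
      int pos = (ax == 0) ? (int)c.x : (ax == 1 ? (int)c.y : (int)c.z);
      if (pos + 1 >= ext) continue;
      R_xlen_t i = center_idx[k];
      if (!pore[i + stride]) continue;
      double rm = std::sqrt(hv[i]) - 0.5;
      if (rm <= 0) continue;
      if (rho[i] >= rm + 0.5 - 1e-12) continue;
      if (rho[i + stride] >= rm + 0.5 - 1e-12) continue;
      Center mc = c;
      if (ax == 0) mc.x += 0.5; else if (ax == 1) mc.y += 0.5; else mc.z += 0.5;
      mc.rho = rm;
      kept.push_back(mc);
    }
  }

  std::sort(kept.begin(), kept.end(),
            [](const Center &a, const Center &b) { return a.rho > b.rho; });

  for (const Center &c : kept) {
    double diam = 2.0 * c.rho;
    double r2 = c.rho * c.rho;
    int zlo = std::max(0, (int)std::ceil(c.z - c.rho - 1e-9));
    int zhi = std::min(n3 - 1, (int)std::floor(c.z + c.rho + 1e-9));
    int ylo = std::max(0, (int)std::ceil(c.y - c.rho - 1e-9));
    int yhi = std::min(n2 - 1, (int)std::floor(c.y + c.rho + 1e-9));
    int xlo = std::max(0, (int)std::ceil(c.x - c.rho - 1e-9));
    int xhi = std::min(n1 - 1, (int)std::floor(c.x + c.rho + 1e-9));
    for (int z = zlo; z <= zhi; ++z) {
      double dz2 = ((double)z - c.z) * ((double)z - c.z);
      for (int y = ylo; y <= yhi; ++y) {
        double dy2 = ((double)y - c.y) * ((double)y - c.y);
        if (dz2 + dy2 > r2 + 1e-9) continue;
        R_xlen_t rowbase = (R_xlen_t)n1 * (y + (R_xlen_t)n2 * z);
        for (int x = xlo; x <= xhi; ++x) {
          double d2 = dz2 + dy2 + ((double)x - c.x) * ((double)x - c.x);
          if (d2 > r2 + 1e-9) continue;
          R_xlen_t i = rowbase + x;
          if (pore[i] && th[i] < diam) th[i] = diam;
        }
      }
    }
  }
  // every pore voxel is covered at least by its own ball
  for (size_t k = 0; k < centers.size(); ++k)
    if (th[center_idx[k]] < 2.0 * centers[k].rho)
      th[center_idx[k]] = 2.0 * centers[k].rho;
  return th;
}

// Brute-force oracle: independent of the transform above. Candidate ball
// centers are the pore voxel centers plus the midpoints of axis-adjacent
// pore-voxel pairs (the same candidate-set definition as the fast path);
// every distance is recomputed by exhaustive search over all background
// voxels (no separable EDT) and every pore voxel is tested against every
// candidate ball. Quadratic; guarded by the caller.
// [[Rcpp::export]]
NumericVector thickness_bruteforce_cpp(LogicalVector pore, IntegerVector dims,
                                       bool border_bg) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> px, py, pz;      // candidate centers (may be half-integer)
  std::vector<int> vx, vy, vz;         // pore voxel coordinates
  std::vector<int> bx, by, bz;         // background voxel coordinates
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        R_xlen_t i = x + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * z);
        if (pore[i]) {
          vx.push_back(x); vy.push_back(y); vz.push_back(z);
          px.push_back(x); py.push_back(y); pz.push_back(z);
          if (x + 1 < n1 && pore[i + 1]) {
            px.push_back(x + 0.5); py.push_back(y); pz.push_back(z);
          }
          if (y + 1 < n2 && pore[i + n1]) {
            px.push_back(x); py.push_back(y + 0.5); pz.push_back(z);
          }
          if (z + 1 < n3 && pore[i + (R_xlen_t)n1 * n2]) {
            px.push_back(x); py.push_back(y); pz.push_back(z + 0.5);
          }
        } else { bx.push_back(x); by.push_back(y); bz.push_back(z); }
      }
  size_t C = px.size(), P = vx.size();
  std::vector<double> rho(C);
  for (size_t c = 0; c < C; ++c) {
    double best = BIG;
    for (size_t b = 0; b < bx.size(); ++b) {
      double dx = px[c] - bx[b], dy = py[c] - by[b], dz = pz[c] - bz[b];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    double d = std::sqrt(best);
    if (border_bg) {
      double db = BIG;
      if (n1 > 1) db = std::min(db, std::min(px[c] + 1.0, (double)n1 - px[c]));
      if (n2 > 1) db = std::min(db, std::min(py[c] + 1.0, (double)n2 - py[c]));
      if (n3 > 1) db = std::min(db, std::min(pz[c] + 1.0, (double)n3 - pz[c]));
      if (db < d) d = db;
    }
    rho[c] = d - 0.5;
    if (rho[c] < 0) rho[c] = 0;
  }
  NumericVector th(N, 0.0);
  for (size_t v = 0; v < P; ++v) {
    double best = 0.0;
    for (size_t c = 0; c < C; ++c) {
      if (2.0 * rho[c] <= best) continue;
      double dx = vx[v] - px[c], dy = vy[v] - py[c], dz = vz[v] - pz[c];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= rho[c] * rho[c] + 1e-9) best = 2.0 * rho[c];
    }
    R_xlen_t i = vx[v] + (R_xlen_t)n1 * (vy[v] + (R_xlen_t)n2 * vz[v]);
    th[i] = best;
  }
  return th;
}

// Connected-component labeling, connectivity 6 or 26 (use a singleton leading
// dimension for 2D masks: 26 is then 8-connectivity, 6 is 4-connectivity).
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  IntegerVector lab(N, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < N; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % n1);
      int y = (int)((cur / n1) % n2);
      int z = (int)(cur / ((R_xlen_t)n1 * n2));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= n1 || yy >= n2 || zz >= n3)
              continue;
            R_xlen_t j = xx + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * zz);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}
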