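// 3-D image primitives shared by the segmentation, cross-section and phantom
// modules.  All volumes are passed as flat vectors in R's column-major order
// with dim = (nz, ny, nx): linear index i = z + nz*(y + ny*x), 0-based here,
// 1-based on the R side.  Foreground connectivity is 26, background/boundary
// connectivity is 6 throughout.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Vol {
  int nz, ny, nx;
  long long n() const { return (long long)nz * ny * nx; }
};

inline Vol as_vol(const IntegerVector& dim) {
  if (dim.size() != 3) stop("dim must have length 3 (nz, ny, nx)");
  Vol v{dim[0], dim[1], dim[2]};
  if (v.nz <= 0 || v.ny <= 0 || v.nx <= 0) stop("volume dimensions must be positive");
  return v;
}

inline long long lidx(int z, int y, int x, const Vol& v) {
  return (long long)z + (long long)v.nz * ((long long)y + (long long)v.ny * x);
}

inline void coords(long long i, const Vol& v, int& z, int& y, int& x) {
  z = (int)(i % v.nz);
  long long r = i / v.nz;
  y = (int)(r % v.ny);
  x = (int)(r / v.ny);
}

struct Nb { int dz, dy, dx; double w; };

std::vector<Nb> make_neighbors(int conn) {
  std::vector<Nb> out;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (conn == 6 && s > 1) continue;
        if (conn == 18 && s > 2) continue;
        out.push_back({dz, dy, dx, std::sqrt((double)(dz * dz + dy * dy + dx * dx))});
      }
  return out;
}

// min-heap entry with FIFO tie-break for determinism
struct QE {
  double key;
  long long order;
  long long idx;
};
struct QECmp {
  bool operator()(const QE& a, const QE& b) const {
    if (a.key != b.key) return a.key > b.key;
    return a.order > b.order;
  }
};
typedef std::priority_queue<QE, std::vector<QE>, QECmp> MinQ;

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  Vol v = as_vol(dim);
  if ((long long)mask.size() != v.n()) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  std::vector<Nb> nb = make_neighbors(connectivity);
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<long long> stack;
  for (long long i = 0; i < (long long)mask.size(); ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      long long c = stack.back();
      stack.pop_back();
      int z, y, x;
      coords(c, v, z, y, x);
      for (const Nb& d : nb) {
        int zz = z + d.dz, yy = y + d.dy, xx = x + d.dx;
        if (zz < 0 || yy < 0 || xx < 0 || zz >= v.nz || yy >= v.ny || xx >= v.nx) continue;
        long long j = lidx(zz, yy, xx, v);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Morphological dilation/erosion with an arbitrary offset set (n x 3 matrix of
// dz,dy,dx).  Out-of-volume samples count as background.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets, bool dilate) {
  Vol v = as_vol(dim);
  if ((long long)mask.size() != v.n()) stop("mask length does not match dim");
  LogicalVector out(mask.size());
  int no = offsets.nrow();
  for (long long i = 0; i < (long long)mask.size(); ++i) {
    int z, y, x;
    coords(i, v, z, y, x);
    bool acc = dilate ? false : true;
    for (int k = 0; k < no; ++k) {
      int zz = z + offsets(k, 0), yy = y + offsets(k, 1), xx = x + offsets(k, 2);
      bool val = false;
      if (zz >= 0 && yy >= 0 && xx >= 0 && zz < v.nz && yy < v.ny && xx < v.nx)
        val = mask[lidx(zz, yy, xx, v)];
      if (dilate) {
        if (val) { acc = true; break; }
      } else {
        if (!val) { acc = false; break; }
      }
    }
    out[i] = acc;
  }
  return out;
}

// Foreground voxels with a 6-neighbour outside the mask (volume border counts
// as outside).  This is the wall-apposed perimeter definition.
// [[Rcpp::export]]
LogicalVector cpp_boundary6(LogicalVector mask, IntegerVector dim) {
  Vol v = as_vol(dim);
  if ((long long)mask.size() != v.n()) stop("mask length does not match dim");
  std::vector<Nb> nb = make_neighbors(6);
  LogicalVector out(mask.size(), false);
  for (long long i = 0; i < (long long)mask.size(); ++i) {
    if (!mask[i]) continue;
    int z, y, x;
    coords(i, v, z, y, x);
    for (const Nb& d : nb) {
      int zz = z + d.dz, yy = y + d.dy, xx = x + d.dx;
      bool outside = (zz < 0 || yy < 0 || xx < 0 || zz >= v.nz || yy >= v.ny || xx >= v.nx);
      if (!outside) outside = !mask[lidx(zz, yy, xx, v)];
      if (outside) { out[i] = true; break; }
    }
  }
  return out;
}

// Chamfer-weighted (1 / sqrt2 / sqrt3) geodesic distance inside `mask` from
// the 1-based seed indices, propagating seed labels.  dist = NA outside the
// mask, Inf for unreachable mask voxels; label = 0 where unreached.
// [[Rcpp::export]]
List cpp_geodesic(LogicalVector mask, IntegerVector dim, IntegerVector seeds,
                  IntegerVector seed_labels, NumericVector seed_dist) {
  Vol v = as_vol(dim);
  if ((long long)mask.size() != v.n()) stop("mask length does not match dim");
  if (seeds.size() != seed_labels.size()) stop("seeds and seed_labels differ in length");
  bool have_d0 = seed_dist.size() == seeds.size();
  std::vector<Nb> nb = make_neighbors(26);
  NumericVector dist(mask.size(), NA_REAL);
  IntegerVector lab(mask.size(), 0);
  for (long long i = 0; i < (long long)mask.size(); ++i)
    if (mask[i]) dist[i] = R_PosInf;
  MinQ q;
  long long ord = 0;
  for (int k = 0; k < seeds.size(); ++k) {
    long long i = (long long)seeds[k] - 1;
    if (i < 0 || i >= (long long)mask.size()) stop("seed index out of range");
    if (!mask[i]) stop("seed voxel lies outside the mask");
    double d0 = have_d0 ? seed_dist[k] : 0.0;
    if (d0 < dist[i]) {
      dist[i] = d0;
      lab[i] = seed_labels[k];
      q.push({d0, ord++, i});
    }
  }
  while (!q.empty()) {
    QE e = q.top();
    q.pop();
    if (e.key > dist[e.idx]) continue;
    int z, y, x;
    coords(e.idx, v, z, y, x);
    for (const Nb& d : nb) {
      int zz = z + d.dz, yy = y + d.dy, xx = x + d.dx;
      if (zz < 0 || yy < 0 || xx < 0 || zz >= v.nz || yy >= v.ny || xx >= v.nx) continue;
      long long j = lidx(zz, yy, xx, v);
      if (!mask[j]) continue;
      double nd = e.key + d.w;
      if (nd < dist[j] - 1e-12) {
        dist[j] = nd;
        lab[j] = lab[e.idx];
        q.push({nd, ord++, j});
      }
    }
  }
  return List::create(_["dist"] = dist, _["label"] = lab);
}

// Marker-constrained priority-flood watershed on an intensity (or gradient)
// image.  Seeds carry labels; flooding proceeds in order of increasing image
// value (6-connectivity); label k may not claim voxels with value >= barrier[k-1].
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector val, IntegerVector dim, IntegerVector seeds,
                            IntegerVector seed_labels, NumericVector barrier) {
  Vol v = as_vol(dim);
  if ((long long)val.size() != v.n()) stop("volume length does not match dim");
  if (seeds.size() != seed_labels.size()) stop("seeds and seed_labels differ in length");
  int nlab = 0;
  for (int k = 0; k < seed_labels.size(); ++k) {
    if (seed_labels[k] < 1) stop("seed labels must be >= 1");
    if (seed_labels[k] > nlab) nlab = seed_labels[k];
  }
  if (barrier.size() != nlab) stop("barrier must have one entry per label");
  std::vector<Nb> nb = make_neighbors(6);
  IntegerVector lab(val.size(), 0);
  MinQ q;
  long long ord = 0;
  for (int k = 0; k < seeds.size(); ++k) {
    long long i = (long long)seeds[k] - 1;
    if (i < 0 || i >= (long long)val.size()) stop("seed index out of range");
    lab[i] = seed_labels[k];
    q.push({val[i], ord++, i});
  }
  while (!q.empty()) {
    QE e = q.top();
    q.pop();
    int l = lab[e.idx];
    int z, y, x;
    coords(e.idx, v, z, y, x);
    for (const Nb& d : nb) {
      int zz = z + d.dz, yy = y + d.dy, xx = x + d.dx;
      if (zz < 0 || yy < 0 || xx < 0 || zz >= v.nz || yy >= v.ny || xx >= v.nx) continue;
      long long j = lidx(zz, yy, xx, v);
      if (lab[j] != 0) continue;
      if (val[j] >= barrier[l - 1]) continue;
      lab[j] = l;
      q.push({val[j], ord++, j});
    }
  }
  return lab;
}

namespace {

// Bertrand/Malandain simple-point test on a 3x3x3 neighbourhood.
// nb27: foreground flags, index = (z+1) + 3*((y+1) + 3*(x+1)), centre at 13.
bool simple_point(const bool* nb27) {
  // Condition A: exactly one 26-component of foreground within N26.
  int compA = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int p = 0; p < 27; ++p) {
    if (p == 13 || !nb27[p] || seen[p]) continue;
    ++compA;
    if (compA > 1) return false;
    int top = 0;
    stack[top++] = p;
    seen[p] = true;
    while (top > 0) {
      int c = stack[--top];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int q = 0; q < 27; ++q) {
        if (q == 13 || !nb27[q] || seen[q]) continue;
        int qz = q % 3, qy = (q / 3) % 3, qx = q / 9;
        if (std::abs(qz - cz) <= 1 && std::abs(qy - cy) <= 1 && std::abs(qx - cx) <= 1) {
          seen[q] = true;
          stack[top++] = q;
        }
      }
    }
  }
  if (compA != 1) return false;
  // Condition B: exactly one 6-component of background within N18 that is
  // 6-adjacent to the centre.
  bool seenB[27] = {false};
  int compB = 0;
  for (int p = 0; p < 27; ++p) {
    if (p == 13 || seenB[p]) continue;
    int pz = p % 3 - 1, py = (p / 3) % 3 - 1, px = p / 9 - 1;
    int s = std::abs(pz) + std::abs(py) + std::abs(px);
    if (s != 1) continue;          // start only from face neighbours
    if (nb27[p]) continue;         // background only
    ++compB;
    if (compB > 1) return false;
    int stackB[27];
    int top = 0;
    stackB[top++] = p;
    seenB[p] = true;
    while (top > 0) {
      int c = stackB[--top];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int q = 0; q < 27; ++q) {
        if (q == 13 || seenB[q] || nb27[q]) continue;
        int qz = q % 3, qy = (q / 3) % 3, qx = q / 9;
        int sq = std::abs(qz - 1) + std::abs(qy - 1) + std::abs(qx - 1);
        if (sq > 2) continue;      // stay inside N18
        int diff = std::abs(qz - cz) + std::abs(qy - cy) + std::abs(qx - cx);
        if (diff == 1) {
          seenB[q] = true;
          stackB[top++] = q;
        }
      }
    }
  }
  return compB == 1;
}

inline void fill_nb27(const LogicalVector& mask, const Vol& v, int z, int y, int x, bool* nb27) {
  int p = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz, ++p) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        if (zz < 0 || yy < 0 || xx < 0 || zz >= v.nz || yy >= v.ny || xx >= v.nx)
          nb27[p] = false;
        else
          nb27[p] = mask[lidx(zz, yy, xx, v)];
      }
}

inline int count_fg26(const bool* nb27) {
  int n = 0;
  for (int p = 0; p < 27; ++p)
    if (p != 13 && nb27[p]) ++n;
  return n;
}

} // namespace

// Chamfer (1/sqrt2/sqrt3) distance from each foreground voxel to the nearest
// background voxel (volume border counts as background).
// [[Rcpp::export]]
NumericVector cpp_dist_to_bg(LogicalVector mask, IntegerVector dim) {
  Vol v = as_vol(dim);
  if ((long long)mask.size() != v.n()) stop("mask length does not match dim");
  std::vector<Nb> nb26 = make_neighbors(26);
  NumericVector dist(mask.size(), NA_REAL);
  MinQ q;
  long long ord = 0;
  for (long long i = 0; i < (long long)mask.size(); ++i) {
    if (!mask[i]) continue;
    dist[i] = R_PosInf;
    int z, y, x;
    coords(i, v, z, y, x);
    double d0 = R_PosInf;
    for (const Nb& d : nb26) {
      int zz = z + d.dz, yy = y + d.dy, xx = x + d.dx;
      bool outside = (zz < 0 || yy < 0 || xx < 0 || zz >= v.nz || yy >= v.ny || xx >= v.nx);
      if (!outside) outside = !mask[lidx(zz, yy, xx, v)];
      if (outside && d.w < d0) d0 = d.w;
    }
    if (d0 < R_PosInf) {
      dist[i] = d0;
      q.push({d0, ord++, i});
    }
  }
  while (!q.empty()) {
    QE e = q.top();
    q.pop();
    if (e.key > dist[e.idx]) continue;
    int z, y, x;
    coords(e.idx, v, z, y, x);
    for (const Nb& d : nb26) {
      int zz = z + d.dz, yy = y + d.dy, xx = x + d.dx;
      if (zz < 0 || yy < 0 || xx < 0 || zz >= v.nz || yy >= v.ny || xx >= v.nx) continue;
      long long j = lidx(zz, yy, xx, v);
      if (Rcpp::LogicalVector::is_na(mask[j]) || !mask[j]) continue;
      double nd = e.key + d.w;
      if (nd < dist[j] - 1e-12) {
        dist[j] = nd;
        q.push({nd, ord++, j});
      }
    }
  }
  return dist;
}

// Distance-ordered homotopic thinning: removes simple points in order of
// increasing chamfer distance to the background, preserving curve endpoints
// (exactly one 26-neighbour).  Yields a centred, unit-width curve skeleton
// for tubular objects.
// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask_in, IntegerVector dim) {
  Vol v = as_vol(dim);
  if ((long long)mask_in.size() != v.n()) stop("mask length does not match dim");
  LogicalVector mask = clone(mask_in);
  std::vector<Nb> nb26 = make_neighbors(26);
  // chamfer distance to background via Dijkstra seeded at boundary voxels
  std::vector<double> dist(mask.size(), R_PosInf);
  MinQ q;
  long long ord = 0;
  for (long long i = 0; i < (long long)mask.size(); ++i) {
    if (!mask[i]) continue;
    int z, y, x;
    coords(i, v, z, y, x);
    double d0 = R_PosInf;
    for (const Nb& d : nb26) {
      int zz = z + d.dz, yy = y + d.dy, xx = x + d.dx;
      bool outside = (zz < 0 || yy < 0 || xx < 0 || zz >= v.nz || yy >= v.ny || xx >= v.nx);
      if (!outside) outside = !mask[lidx(zz, yy, xx, v)];
      if (outside && d.w < d0) d0 = d.w;
    }
    if (d0 < R_PosInf) {
      dist[i] = d0;
      q.push({d0, ord++, i});
    }
  }
  {
    MinQ qd = q; // relax full distance map first (copy keeps boundary queue for reuse)
    while (!qd.empty()) {
      QE e = qd.top();
      qd.pop();
      if (e.key > dist[e.idx]) continue;
      int z, y, x;
      coords(e.idx, v, z, y, x);
      for (const Nb& d : nb26) {
        int zz = z + d.dz, yy = y + d.dy, xx = x + d.dx;
        if (zz < 0 || yy < 0 || xx < 0 || zz >= v.nz || yy >= v.ny || xx >= v.nx) continue;
        long long j = lidx(zz, yy, xx, v);
        if (!mask[j]) continue;
        double nd = e.key + d.w;
        if (nd < dist[j] - 1e-12) {
          dist[j] = nd;
          qd.push({nd, ord++, j});
        }
      }
    }
  }
  // homotopic thinning ordered by the (frozen) distance map
  bool nb27[27];
  while (!q.empty()) {
    QE e = q.top();
    q.pop();
    if (!mask[e.idx]) continue;
    int z, y, x;
    coords(e.idx, v, z, y, x);
    fill_nb27(mask, v, z, y, x, nb27);
    int nfg = count_fg26(nb27);
    if (nfg <= 1) continue;              // curve endpoint or isolated: keep
    if (!simple_point(nb27)) continue;   // deletion would change topology
    mask[e.idx] = false;
    for (const Nb& d : nb26) {
      int zz = z + d.dz, yy = y + d.dy, xx = x + d.dx;
      if (zz < 0 || yy < 0 || xx < 0 || zz >= v.nz || yy >= v.ny || xx >= v.nx) continue;
      long long j = lidx(zz, yy, xx, v);
      if (mask[j]) q.push({dist[j], ord++, j});
    }
  }
  return mask;
}

// Separable Gaussian smoothing, reflecting at the volume borders.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim, double sigma) {
  Vol v = as_vol(dim);
  if ((long long)vol.size() != v.n()) stop("volume length does not match dim");
  if (sigma <= 0) return clone(vol);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& kv : k) kv /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  int n[3] = {v.nz, v.ny, v.nx};
  long long stride[3] = {1, (long long)v.nz, (long long)v.nz * v.ny};
  for (int ax = 0; ax < 3; ++ax) {
    int na = n[ax];
    long long st = stride[ax];
    long long nlines = v.n() / na;
    for (long long line = 0; line < nlines; ++line) {
      // base index of this line
      long long rem = line, base = 0;
      for (int o = 0; o < 3; ++o) {
        if (o == ax) continue;
        long long sz = n[o];
        base += (rem % sz) * stride[o];
        rem /= sz;
      }
      for (int i = 0; i < na; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) {
          int p = i + j;
          if (p < 0) p = -p - 1;
          if (p >= na) p = 2 * na - p - 1;
          acc += k[j + r] * a[base + (long long)p * st];
        }
        b[base + (long long)i * st] = acc;
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
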