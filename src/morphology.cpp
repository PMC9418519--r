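// 3D binary-image primitives used by the labeling / watershed stages:
// connected-component labeling (6/26), Euclidean distance transform
// (Felzenszwalb-Huttenlocher separable parabola method), marker-based
// watershed on the distance transform with h-maxima marker suppression,
// per-label bounding boxes and inter-label contact areas.
//
// Volumes are R arrays in column-major order, dim = (d1, d2, d3).
// Outside the volume counts as background (solid) everywhere.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <map>
#include <cstdint>
using namespace Rcpp;

static const double INF = 1e30;

struct Dims {
  int d1, d2, d3;
  R_xlen_t n;
};

static inline R_xlen_t idx3(const Dims& d, int i, int j, int k) {
  return (R_xlen_t)i + (R_xlen_t)d.d1 * ((R_xlen_t)j + (R_xlen_t)d.d2 * k);
}

// neighbor offsets for 6- or 26-connectivity
static std::vector<std::array<int, 3> > neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        int man = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (man == 0) continue;
        if (connectivity == 6 && man != 1) continue;
        offs.push_back({dy, dx, dz});
      }
  return offs;
}

// [[Rcpp::export(name = ".cc_label3")]]
IntegerVector cc_label3(LogicalVector mask, IntegerVector dim, int connectivity) {
  Dims d{dim[0], dim[1], dim[2], (R_xlen_t)dim[0] * dim[1] * dim[2]};
  if (mask.size() != d.n) stop("mask length does not match dim");
  std::vector<std::array<int, 3> > offs = neighbor_offsets(connectivity);
  IntegerVector lab(d.n, 0);
  std::vector<R_xlen_t> stack;
  int K = 0;
  for (int k = 0; k < d.d3; ++k)
    for (int j = 0; j < d.d2; ++j)
      for (int i = 0; i < d.d1; ++i) {
        R_xlen_t p = idx3(d, i, j, k);
        if (!mask[p] || lab[p]) continue;
        ++K;
        lab[p] = K;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          R_xlen_t q = stack.back();
          stack.pop_back();
          int qi = (int)(q % d.d1);
          int qj = (int)((q / d.d1) % d.d2);
          int qk = (int)(q / ((R_xlen_t)d.d1 * d.d2));
          for (size_t o = 0; o < offs.size(); ++o) {
            int ni = qi + offs[o][0], nj = qj + offs[o][1], nk = qk + offs[o][2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= d.d1 || nj >= d.d2 || nk >= d.d3)
              continue;
            R_xlen_t np = idx3(d, ni, nj, nk);
            if (mask[np] && !lab[np]) {
              lab[np] = K;
              stack.push_back(np);
            }
          }
        }
      }
  lab.attr("K") = K;
  lab.attr("dim") = dim;
  return lab;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher),
// with virtual background sites just outside both line ends.
static void dt1d(const std::vector<double>& f, std::vector<double>& out) {
  int n = (int)f.size();
  std::vector<int> v(n + 2);
  std::vector<double> z(n + 3);
  // augmented sites: -1 and n with f = 0 (outside is background)
  std::vector<double> g(n + 2);
  auto site = [&](int s) { return s - 1; };  // site index -> coordinate (-1..n)
  g[0] = 0.0;
  for (int q = 0; q < n; ++q) g[q + 1] = f[q];
  g[n + 1] = 0.0;
  int m = n + 2;
  int kk = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < m; ++q) {
    double xq = site(q);
    double s;
    while (true) {
      double xv = site(v[kk]);
      s = ((g[q] + xq * xq) - (g[v[kk]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s <= z[kk]) {
        --kk;
      } else {
        break;
      }
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q;
    while (z[kk + 1] < xq) ++kk;
    double xv = site(v[kk]);
    out[q] = (xq - xv) * (xq - xv) + g[v[kk]];
  }
}

// [[Rcpp::export(name = ".edt_sq3")]]
NumericVector edt_sq3(LogicalVector mask, IntegerVector dim) {
  Dims d{dim[0], dim[1], dim[2], (R_xlen_t)dim[0] * dim[1] * dim[2]};
  if (mask.size() != d.n) stop("mask length does not match dim");
  NumericVector D(d.n);
  for (R_xlen_t p = 0; p < d.n; ++p) D[p] = mask[p] ? INF : 0.0;
  std::vector<double> f, out;
  // pass along dim1
  f.resize(d.d1);
  out.resize(d.d1);
  for (int k = 0; k < d.d3; ++k)
    for (int j = 0; j < d.d2; ++j) {
      for (int i = 0; i < d.d1; ++i) f[i] = D[idx3(d, i, j, k)];
      dt1d(f, out);
      for (int i = 0; i < d.d1; ++i) D[idx3(d, i, j, k)] = out[i];
    }
  // pass along dim2
  f.resize(d.d2);
  out.resize(d.d2);
  for (int k = 0; k < d.d3; ++k)
    for (int i = 0; i < d.d1; ++i) {
      for (int j = 0; j < d.d2; ++j) f[j] = D[idx3(d, i, j, k)];
      dt1d(f, out);
      for (int j = 0; j < d.d2; ++j) D[idx3(d, i, j, k)] = out[j];
    }
  // pass along dim3
  f.resize(d.d3);
  out.resize(d.d3);
  for (int j = 0; j < d.d2; ++j)
    for (int i = 0; i < d.d1; ++i) {
      for (int k = 0; k < d.d3; ++k) f[k] = D[idx3(d, i, j, k)];
      dt1d(f, out);
      for (int k = 0; k < d.d3; ++k) D[idx3(d, i, j, k)] = out[k];
    }
  D.attr("dim") = dim;
  return D;
}

// grayscale reconstruction by dilation of `marker` under `maskimg`
// (26-connected), sequential forward/backward raster sweeps to stability.
static void grayrec(std::vector<double>& m, const NumericVector& g, const Dims& d) {
  bool changed = true;
  int sweeps = 0;
  while (changed && sweeps < 1000) {
    changed = false;
    ++sweeps;
    // forward sweep: neighbors with lower raster index
    for (int k = 0; k < d.d3; ++k)
      for (int j = 0; j < d.d2; ++j)
        for (int i = 0; i < d.d1; ++i) {
          R_xlen_t p = idx3(d, i, j, k);
          double best = m[p];
          for (int dz = -1; dz <= 0; ++dz)
            for (int dx = -1; dx <= 1; ++dx)
              for (int dy = -1; dy <= 1; ++dy) {
                if (dz == 0 && (dx > 0 || (dx == 0 && dy >= 0))) continue;
                int ni = i + dy, nj = j + dx, nk = k + dz;
                if (ni < 0 || nj < 0 || nk < 0 || ni >= d.d1 || nj >= d.d2 || nk >= d.d3)
                  continue;
                double v = m[idx3(d, ni, nj, nk)];
                if (v > best) best = v;
              }
          best = std::min(best, (double)g[p]);
          if (best > m[p]) {
            m[p] = best;
            changed = true;
          }
        }
    // backward sweep
    for (int k = d.d3 - 1; k >= 0; --k)
      for (int j = d.d2 - 1; j >= 0; --j)
        for (int i = d.d1 - 1; i >= 0; --i) {
          R_xlen_t p = idx3(d, i, j, k);
          double best = m[p];
          for (int dz = 0; dz <= 1; ++dz)
            for (int dx = -1; dx <= 1; ++dx)
              for (int dy = -1; dy <= 1; ++dy) {
                if (dz == 0 && (dx < 0 || (dx == 0 && dy <= 0))) continue;
                int ni = i + dy, nj = j + dx, nk = k + dz;
                if (ni < 0 || nj < 0 || nk < 0 || ni >= d.d1 || nj >= d.d2 || nk >= d.d3)
                  continue;
                double v = m[idx3(d, ni, nj, nk)];
                if (v > best) best = v;
              }
          best = std::min(best, (double)g[p]);
          if (best > m[p]) {
            m[p] = best;
            changed = true;
          }
        }
  }
}

struct QItem {
  double d;
  uint64_t seq;
  R_xlen_t p;
  int lab;
};
struct QCmp {
  // max-heap on distance; FIFO (insertion order) on ties for flat fronts
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.d != b.d) return a.d < b.d;
    return a.seq > b.seq;
  }
};

// [[Rcpp::export(name = ".watershed3")]]
IntegerVector watershed3(LogicalVector mask, IntegerVector dim, double hmin) {
  Dims d{dim[0], dim[1], dim[2], (R_xlen_t)dim[0] * dim[1] * dim[2]};
  if (mask.size() != d.n) stop("mask length does not match dim");
  if (hmin <= 0) hmin = 1e-3;  // h = 0: split at every regional maximum
  NumericVector D2 = edt_sq3(mask, dim);
  NumericVector D(d.n);
  for (R_xlen_t p = 0; p < d.n; ++p) D[p] = std::sqrt(D2[p]);
  // h-maxima: reconstruct (D - h) under D; surviving peaks keep D - rec == h
  std::vector<double> rec(d.n);
  for (R_xlen_t p = 0; p < d.n; ++p) rec[p] = mask[p] ? D[p] - hmin : 0.0;
  grayrec(rec, D, d);
  LogicalVector mk(d.n);
  for (R_xlen_t p = 0; p < d.n; ++p)
    mk[p] = mask[p] && (D[p] - rec[p] >= hmin - 1e-6);
  IntegerVector seeds = cc_label3(mk, dim, 26);
  int K = as<int>(seeds.attr("K"));
  IntegerVector lab(d.n, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  uint64_t seq = 0;
  std::vector<std::array<int, 3> > offs = neighbor_offsets(26);
  for (int k = 0; k < d.d3; ++k)
    for (int j = 0; j < d.d2; ++j)
      for (int i = 0; i < d.d1; ++i) {
        R_xlen_t p = idx3(d, i, j, k);
        if (seeds[p]) {
          lab[p] = seeds[p];
          pq.push({D[p], seq++, p, seeds[p]});
        }
      }
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int qi = (int)(it.p % d.d1);
    int qj = (int)((it.p / d.d1) % d.d2);
    int qk = (int)(it.p / ((R_xlen_t)d.d1 * d.d2));
    for (size_t o = 0; o < offs.size(); ++o) {
      int ni = qi + offs[o][0], nj = qj + offs[o][1], nk = qk + offs[o][2];
      if (ni < 0 || nj < 0 || nk < 0 || ni >= d.d1 || nj >= d.d2 || nk >= d.d3)
        continue;
      R_xlen_t np = idx3(d, ni, nj, nk);
      if (mask[np] && !lab[np]) {
        lab[np] = it.lab;
        pq.push({D[np], seq++, np, it.lab});
      }
    }
  }
  lab.attr("K") = K;
  lab.attr("dim") = dim;
  return lab;
}

// [[Rcpp::export(name = ".label_bbox")]]
IntegerMatrix label_bbox(IntegerVector lab, IntegerVector dim, int K) {
  Dims d{dim[0], dim[1], dim[2], (R_xlen_t)dim[0] * dim[1] * dim[2]};
  IntegerMatrix bb(K, 7);
  for (int r = 0; r < K; ++r) {
    bb(r, 0) = d.d1 + 1; bb(r, 1) = 0;
    bb(r, 2) = d.d2 + 1; bb(r, 3) = 0;
    bb(r, 4) = d.d3 + 1; bb(r, 5) = 0;
    bb(r, 6) = 0;
  }
  for (int k = 0; k < d.d3; ++k)
    for (int j = 0; j < d.d2; ++j)
      for (int i = 0; i < d.d1; ++i) {
        int L = lab[idx3(d, i, j, k)];
        if (L <= 0) continue;
        if (L > K) stop("label exceeds K");
        int r = L - 1;
        if (i + 1 < bb(r, 0)) bb(r, 0) = i + 1;
        if (i + 1 > bb(r, 1)) bb(r, 1) = i + 1;
        if (j + 1 < bb(r, 2)) bb(r, 2) = j + 1;
        if (j + 1 > bb(r, 3)) bb(r, 3) = j + 1;
        if (k + 1 < bb(r, 4)) bb(r, 4) = k + 1;
        if (k + 1 > bb(r, 5)) bb(r, 5) = k + 1;
        bb(r, 6) += 1;
      }
  return bb;
}

// face-adjacent (6-connectivity) contacts between distinct labels: face
// counts per normal direction (for the Cauchy-projection area estimate,
// which removes the staircase inflation of oblique cuts) and the mean
// position of the contact, per label pair
// [[Rcpp::export(name = ".contact_table")]]
DataFrame contact_table(IntegerVector lab, IntegerVector dim) {
  Dims d{dim[0], dim[1], dim[2], (R_xlen_t)dim[0] * dim[1] * dim[2]};
  // per pair: n_y, n_x, n_z face counts, then position sums
  std::map<std::pair<int, int>, std::array<double, 6> > acc;
  int step[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int k = 0; k < d.d3; ++k)
    for (int j = 0; j < d.d2; ++j)
      for (int i = 0; i < d.d1; ++i) {
        int a = lab[idx3(d, i, j, k)];
        if (a <= 0) continue;
        for (int s = 0; s < 3; ++s) {
          int ni = i + step[s][0], nj = j + step[s][1], nk = k + step[s][2];
          if (ni >= d.d1 || nj >= d.d2 || nk >= d.d3) continue;
          int b = lab[idx3(d, ni, nj, nk)];
          if (b <= 0 || b == a) continue;
          std::pair<int, int> key(std::min(a, b), std::max(a, b));
          std::array<double, 6>& v = acc[key];
          v[s] += 1.0;
          v[3] += 0.5 * (i + ni) + 1.0;  // 1-based face position
          v[4] += 0.5 * (j + nj) + 1.0;
          v[5] += 0.5 * (k + nk) + 1.0;
        }
      }
  int n = (int)acc.size();
  IntegerVector li(n), lj(n), nf(n);
  NumericVector cy(n), cx(n), cz(n), af(n);
  int r = 0;
  for (std::map<std::pair<int, int>, std::array<double, 6> >::iterator it = acc.begin();
       it != acc.end(); ++it, ++r) {
    li[r] = it->first.first;
    lj[r] = it->first.second;
    double ny = it->second[0], nx = it->second[1], nz = it->second[2];
    double tot = ny + nx + nz;
    nf[r] = (int)tot;
    af[r] = std::sqrt(ny * ny + nx * nx + nz * nz);  // area in face units
    cy[r] = it->second[3] / tot;
    cx[r] = it->second[4] / tot;
    cz[r] = it->second[5] / tot;
  }
  return DataFrame::create(_["i"] = li, _["j"] = lj, _["n_faces"] = nf,
                           _["area_faces"] = af,
                           _["y"] = cy, _["x"] = cx, _["z"] = cz);
}
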