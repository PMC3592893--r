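#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double BIG = 1e15;

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -BIG; z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance from every pixel to the nearest pixel
// where mask is FALSE.  Grid is row-major: idx = r*nc + c.  If mask is TRUE
// everywhere the distances saturate at BIG.
static std::vector<double> edtSqGrid(const std::vector<char>& mask, int nr, int nc) {
  int m = std::max(nr, nc);
  std::vector<double> g((size_t)nr * nc), out((size_t)nr * nc);
  std::vector<double> f(m), d(m);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask[(size_t)r * nc + c] ? BIG : 0.0;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g[(size_t)r * nc + c] = d[r];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g[(size_t)r * nc + c];
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out[(size_t)r * nc + c] = std::min(d[c], BIG);
  }
  return out;
}

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

struct QE { double d; long long seq; int lab; int idx; };
struct QCmp {
  bool operator()(const QE& a, const QE& b) const {
    if (a.d != b.d) return a.d < b.d;  // deeper basin floor first
    return a.seq > b.seq;              // then first-in-first-out (Meyer)
  }
};

// Watershed of the negated EDT of the candidate mask.  Basin seeds are the
// regional maxima plateaus of the distance transform, labelled in row-major
// order of each plateau's first pixel; flooding proceeds from high distance
// to low, ties resolved first-in-first-out (Meyer), with pushes made in a
// fixed row-major scan/neighbour order so the result is deterministic.
// Every candidate pixel receives exactly one label; non-candidates stay 0.
static std::vector<int> watershedGrid(const std::vector<char>& cand, int nr, int nc,
                                      int* nlabOut) {
  size_t n = (size_t)nr * nc;
  std::vector<int> lab(n, 0);
  bool any = false;
  for (size_t i = 0; i < n; ++i) if (cand[i]) { any = true; break; }
  if (nlabOut) *nlabOut = 0;
  if (!any) return lab;

  std::vector<double> d = edtSqGrid(cand, nr, nc);

  // Regional maxima plateaus (8-connected components of equal distance with
  // no strictly greater candidate neighbour).
  std::vector<char> seen(n, 0);
  std::vector<int> stack, members;
  int nextLab = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int i = r * nc + c;
      if (!cand[i] || seen[i]) continue;
      double h = d[i];
      bool isMax = true;
      stack.clear(); members.clear();
      stack.push_back(i); seen[i] = 1;
      while (!stack.empty()) {
        int j = stack.back(); stack.pop_back();
        members.push_back(j);
        int jr = j / nc, jc = j % nc;
        for (int k = 0; k < 8; ++k) {
          int qr = jr + DR8[k], qc = jc + DC8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          int q = qr * nc + qc;
          if (!cand[q]) continue;
          if (d[q] > h) isMax = false;
          else if (d[q] == h && !seen[q]) { seen[q] = 1; stack.push_back(q); }
        }
      }
      if (isMax) {
        ++nextLab;
        for (size_t k = 0; k < members.size(); ++k) lab[members[k]] = nextLab;
      }
    }
  }

  std::priority_queue<QE, std::vector<QE>, QCmp> pq;
  long long seq = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int i = r * nc + c;
      if (lab[i] == 0) continue;
      for (int k = 0; k < 8; ++k) {
        int qr = r + DR8[k], qc = c + DC8[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int q = qr * nc + qc;
        if (cand[q] && lab[q] == 0) pq.push(QE{d[q], seq++, lab[i], q});
      }
    }
  }
  while (!pq.empty()) {
    QE e = pq.top(); pq.pop();
    if (lab[e.idx] != 0) continue;
    lab[e.idx] = e.lab;
    int r = e.idx / nc, c = e.idx % nc;
    for (int k = 0; k < 8; ++k) {
      int qr = r + DR8[k], qc = c + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      int q = qr * nc + qc;
      if (cand[q] && lab[q] == 0) pq.push(QE{d[q], seq++, e.lab, q});
    }
  }
  if (nlabOut) *nlabOut = nextLab;
  return lab;
}

static std::vector<char> toGrid(const LogicalMatrix& m) {
  int nr = m.nrow(), nc = m.ncol();
  std::vector<char> g((size_t)nr * nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      g[(size_t)r * nc + c] = m(r, c) ? 1 : 0;
  return g;
}

// [[Rcpp::export(name = ".edtCpp")]]
NumericMatrix edtCpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> g = toGrid(mask);
  std::vector<double> d = edtSqGrid(g, nr, nc);
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = std::sqrt(d[(size_t)r * nc + c]);
  return out;
}

// [[Rcpp::export(name = ".watershedCpp")]]
IntegerMatrix watershedCpp(LogicalMatrix cand) {
  int nr = cand.nrow(), nc = cand.ncol();
  std::vector<char> g = toGrid(cand);
  int nlab = 0;
  std::vector<int> lab = watershedGrid(g, nr, nc, &nlab);
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = lab[(size_t)r * nc + c];
  return out;
}

// 8-connected component labelling; labels numbered by the row-major order of
// each component's first pixel.
// [[Rcpp::export(name = ".label8Cpp")]]
IntegerMatrix label8Cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> g = toGrid(mask);
  std::vector<int> lab((size_t)nr * nc, 0);
  std::vector<int> stack;
  int nextLab = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int i = r * nc + c;
      if (!g[i] || lab[i]) continue;
      ++nextLab;
      stack.clear(); stack.push_back(i); lab[i] = nextLab;
      while (!stack.empty()) {
        int j = stack.back(); stack.pop_back();
        int jr = j / nc, jc = j % nc;
        for (int k = 0; k < 8; ++k) {
          int qr = jr + DR8[k], qc = jc + DC8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          int q = qr * nc + qc;
          if (g[q] && !lab[q]) { lab[q] = nextLab; stack.push_back(q); }
        }
      }
    }
  }
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = lab[(size_t)r * nc + c];
  return out;
}

// Full 256-threshold voting sweep for one window.  For each threshold t in
// 1..256 the candidate mask {phase < t} is watershed-partitioned and every
// sub-region passing the three acceptance criteria (seed overlap fraction,
// non-candidate fraction, not touching the window border) adds one vote to
// its pixels.  Thresholds that add no new candidate pixels reuse the
// previous accepted mask (the candidate mask, and hence the result, is
// identical).
// [[Rcpp::export(name = ".compositeSweepCpp")]]
NumericMatrix compositeSweepCpp(IntegerMatrix phase, LogicalMatrix seed,
                                double seedOverlapMin, double noncellMax) {
  int nr = phase.nrow(), nc = phase.ncol();
  size_t n = (size_t)nr * nc;
  std::vector<char> seedG = toGrid(seed);
  std::vector<int> ph(n);
  std::vector<std::vector<int> > byVal(256);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int v = phase(r, c);
      if (v < 0 || v > 255)
        stop("phase values must lie in [0, 255]");
      ph[(size_t)r * nc + c] = v;
    }
  }
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      byVal[phase(r, c)].push_back(r * nc + c);

  std::vector<char> cand(n, 0);
  std::vector<char> acc(n, 0);
  std::vector<double> raw(n, 0.0);
  size_t candCount = 0;

  for (int t = 1; t <= 256; ++t) {
    const std::vector<int>& fresh = byVal[t - 1];
    if (!fresh.empty() || t == 1) {
      for (size_t k = 0; k < fresh.size(); ++k) cand[fresh[k]] = 1;
      candCount += fresh.size();
      std::fill(acc.begin(), acc.end(), 0);
      if (candCount > 0) {
        int nlab = 0;
        std::vector<int> lab = watershedGrid(cand, nr, nc, &nlab);
        if (nlab > 0) {
          std::vector<double> area(nlab + 1, 0.0), ov(nlab + 1, 0.0),
                              noncell(nlab + 1, 0.0);
          std::vector<char> border(nlab + 1, 0);
          for (int r = 0; r < nr; ++r) {
            for (int c = 0; c < nc; ++c) {
              int L = lab[(size_t)r * nc + c];
              if (!L) continue;
              area[L] += 1.0;
              if (seedG[(size_t)r * nc + c]) ov[L] += 1.0;
              if (!cand[(size_t)r * nc + c]) noncell[L] += 1.0; // regions are
              // subsets of the candidate mask, so this stays 0; kept for the
              // literal criterion.
              if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1) border[L] = 1;
            }
          }
          std::vector<char> keep(nlab + 1, 0);
          for (int L = 1; L <= nlab; ++L)
            keep[L] = (ov[L] / area[L] > seedOverlapMin) &&
                      (noncell[L] / area[L] < noncellMax) && !border[L];
          for (size_t i = 0; i < n; ++i)
            if (lab[i] && keep[lab[i]]) acc[i] = 1;
        }
      }
    }
    for (size_t i = 0; i < n; ++i) raw[i] += acc[i];
  }

  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = raw[(size_t)r * nc + c];
  return out;
}
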