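// Low-level image operators: flat disk erosion/dilation, grayscale
// reconstruction, regional minima, connected components, seeded watershed
// with ridge lines, binary thinning, separable convolution, Sobel gradients.
// Matrices are R numeric matrices (column-major); 8-connectivity throughout.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

static const int DR8[8] = { -1, -1, -1,  0, 0,  1, 1, 1 };
static const int DC8[8] = { -1,  0,  1, -1, 1, -1, 0, 1 };

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 1-D min filter with window halfwidth h along each column (contiguous in
// memory), replicate border; van Herk/Gil-Werman, O(1) per pixel.
static void minfilt_cols(const NumericMatrix& in, NumericMatrix& out, int h) {
  const int nr = in.nrow(), nc = in.ncol();
  if (h == 0) {
    std::copy(in.begin(), in.end(), out.begin());
    return;
  }
  const int w = 2 * h + 1;
  const int n = nr + 2 * h;
  std::vector<double> pad(n), g(n), s(n);
  for (int c = 0; c < nc; ++c) {
    const double* ip = &in[(size_t)c * nr];
    double* op = &out[(size_t)c * nr];
    for (int i = 0; i < nr; ++i) pad[h + i] = ip[i];
    for (int i = 0; i < h; ++i) {
      pad[i] = ip[0];
      pad[h + nr + i] = ip[nr - 1];
    }
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      g[i] = (cnt == 0) ? pad[i] : std::min(g[i - 1], pad[i]);
      if (++cnt == w) cnt = 0;
    }
    cnt = (n - 1) % w;
    for (int i = n - 1; i >= 0; --i) {
      s[i] = (cnt == w - 1 || i == n - 1) ? pad[i] : std::min(s[i + 1], pad[i]);
      if (--cnt < 0) cnt = w - 1;
    }
    for (int i = 0; i < nr; ++i)
      op[i] = std::min(s[i], g[i + 2 * h]);
  }
}

// Erosion (or dilation) by a discrete Euclidean disk {(dr,dc): dr^2+dc^2 <= r^2},
// decomposed into per-column-offset vertical min filters.
// [[Rcpp::export]]
NumericMatrix cpp_morph_disk(NumericMatrix img, int radius, bool dilate) {
  const int nr = img.nrow(), nc = img.ncol();
  if (radius < 1) stop("structuring element radius must be >= 1");
  NumericMatrix src(nr, nc);
  if (dilate) {
    for (int i = 0; i < nr * nc; ++i) src[i] = -img[i];
  } else {
    src = clone(img);
  }
  // group column offsets by their vertical halfwidth so each van Herk pass
  // is shared between +dc and -dc
  std::map< int, std::vector<int> > byh;
  for (int dc = -radius; dc <= radius; ++dc) {
    int hh = (int)std::floor(std::sqrt((double)radius * radius -
                                       (double)dc * dc) + 1e-9);
    byh[hh].push_back(dc);
  }
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), R_PosInf);
  NumericMatrix tmp(nr, nc);
  for (std::map< int, std::vector<int> >::iterator it = byh.begin();
       it != byh.end(); ++it) {
    minfilt_cols(src, tmp, it->first);
    const std::vector<int>& dcs = it->second;
    for (size_t k = 0; k < dcs.size(); ++k) {
      for (int c = 0; c < nc; ++c) {
        int cs = clampi(c + dcs[k], 0, nc - 1);  // replicate border
        const double* tp = &tmp[(size_t)cs * nr];
        double* op = &out[(size_t)c * nr];
        for (int r = 0; r < nr; ++r)
          if (tp[r] < op[r]) op[r] = tp[r];
      }
    }
  }
  if (dilate)
    for (int i = 0; i < nr * nc; ++i) out[i] = -out[i];
  return out;
}

// Grayscale reconstruction by dilation of `marker` under `mask`
// (hybrid raster-scan + FIFO propagation).
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J(nr, nc);
  for (int i = 0; i < nr * nc; ++i) J[i] = std::min(marker[i], mask[i]);

  // forward raster scan (column-major storage order); visited neighbours of
  // (r, c) are (r-1, c) and rows r-1..r+1 of column c-1
  for (int c = 0; c < nc; ++c) {
    double* Jc = &J[(size_t)c * nr];
    const double* Mc = &mask[(size_t)c * nr];
    const double* Jp = c > 0 ? &J[(size_t)(c - 1) * nr] : NULL;
    for (int r = 0; r < nr; ++r) {
      double m = Jc[r];
      if (r > 0 && Jc[r - 1] > m) m = Jc[r - 1];
      if (Jp) {
        if (Jp[r] > m) m = Jp[r];
        if (r > 0 && Jp[r - 1] > m) m = Jp[r - 1];
        if (r + 1 < nr && Jp[r + 1] > m) m = Jp[r + 1];
      }
      Jc[r] = m < Mc[r] ? m : Mc[r];
    }
  }
  // backward scan + queue seeding
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    double* Jc = &J[(size_t)c * nr];
    const double* Mc = &mask[(size_t)c * nr];
    const double* Jn = c + 1 < nc ? &J[(size_t)(c + 1) * nr] : NULL;
    const double* Mn = c + 1 < nc ? &mask[(size_t)(c + 1) * nr] : NULL;
    for (int r = nr - 1; r >= 0; --r) {
      double m = Jc[r];
      if (r + 1 < nr && Jc[r + 1] > m) m = Jc[r + 1];
      if (Jn) {
        if (Jn[r] > m) m = Jn[r];
        if (r > 0 && Jn[r - 1] > m) m = Jn[r - 1];
        if (r + 1 < nr && Jn[r + 1] > m) m = Jn[r + 1];
      }
      double jv = m < Mc[r] ? m : Mc[r];
      Jc[r] = jv;
      bool push = false;
      if (r + 1 < nr && Jc[r + 1] < jv && Jc[r + 1] < Mc[r + 1]) {
        push = true;
      } else if (Jn) {
        if (Jn[r] < jv && Jn[r] < Mn[r]) push = true;
        else if (r > 0 && Jn[r - 1] < jv && Jn[r - 1] < Mn[r - 1]) push = true;
        else if (r + 1 < nr && Jn[r + 1] < jv && Jn[r + 1] < Mn[r + 1]) push = true;
      }
      if (push) fifo.push(c * nr + r);
    }
  }
  while (!fifo.empty()) {
    int p = fifo.front();
    fifo.pop();
    int r = p % nr, c = p / nr;
    double jp = J(r, c);
    for (int k = 0; k < 8; ++k) {
      int qr = r + DR8[k], qc = c + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (J(qr, qc) < jp && mask(qr, qc) != J(qr, qc)) {
        J(qr, qc) = std::min(jp, mask(qr, qc));
        fifo.push(qc * nr + qr);
      }
    }
  }
  return J;
}

// Regional minima (8-connected flat zones with no lower neighbor),
// labeled 1..k; non-minimum pixels get 0.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_minima(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<char> visited((size_t)nr * nc, 0);
  std::vector<int> plateau;
  std::queue<int> q;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      int p0 = c0 * nr + r0;
      if (visited[p0]) continue;
      double v = img[p0];
      bool ismin = true;
      plateau.clear();
      visited[p0] = 1;
      q.push(p0);
      while (!q.empty()) {
        int p = q.front();
        q.pop();
        plateau.push_back(p);
        int r = p % nr, c = p / nr;
        for (int k = 0; k < 8; ++k) {
          int qr = r + DR8[k], qc = c + DC8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          int pq = qc * nr + qr;
          double vq = img[pq];
          if (vq < v) {
            ismin = false;
          } else if (vq == v && !visited[pq]) {
            visited[pq] = 1;
            q.push(pq);
          }
        }
      }
      if (ismin) {
        ++next;
        for (size_t i = 0; i < plateau.size(); ++i) lab[plateau[i]] = next;
      }
    }
  }
  return lab;
}

// 8-connected component labeling of a logical mask.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::queue<int> q;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      int p0 = c0 * nr + r0;
      if (!mask[p0] || lab[p0]) continue;
      ++next;
      lab[p0] = next;
      q.push(p0);
      while (!q.empty()) {
        int p = q.front();
        q.pop();
        int r = p % nr, c = p / nr;
        for (int k = 0; k < 8; ++k) {
          int qr = r + DR8[k], qc = c + DC8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          int pq = qc * nr + qr;
          if (mask[pq] && !lab[pq]) {
            lab[pq] = next;
            q.push(pq);
          }
        }
      }
    }
  }
  return lab;
}

struct WsEntry {
  double v;
  long long ord;
  int idx;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.v != b.v) return a.v > b.v;  // min-heap on value
    return a.ord > b.ord;              // FIFO among equal values
  }
};

// Seeded watershed (Meyer flooding) on segmentation function `f` from
// integer seed labels (> 0). Ridge pixels and pixels unreachable from any
// seed get 0. Deterministic: ties broken by insertion order.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix f, IntegerMatrix seeds) {
  const int nr = f.nrow(), nc = f.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("seed and image dimensions differ");
  IntegerMatrix lab = clone(seeds);
  std::vector<char> inq((size_t)nr * nc, 0);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long long ord = 0;
  const int WSHED = -1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        int qr = r + DR8[k], qc = c + DC8[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int pq_ = qc * nr + qr;
        if (lab[pq_] == 0 && !inq[pq_]) {
          inq[pq_] = 1;
          WsEntry e;
          e.v = f[pq_];
          e.ord = ord++;
          e.idx = pq_;
          pq.push(e);
        }
      }
    }
  }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    int p = e.idx;
    if (lab[p] != 0) continue;
    int r = p % nr, c = p / nr;
    int found = 0;
    bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      int qr = r + DR8[k], qc = c + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      int lq = lab(qr, qc);
      if (lq > 0) {
        if (found == 0) {
          found = lq;
        } else if (found != lq) {
          conflict = true;
          break;
        }
      }
    }
    if (found == 0 || conflict) {
      lab[p] = WSHED;
      continue;
    }
    lab[p] = found;
    for (int k = 0; k < 8; ++k) {
      int qr = r + DR8[k], qc = c + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      int pq_ = qc * nr + qr;
      if (lab[pq_] == 0 && !inq[pq_]) {
        inq[pq_] = 1;
        WsEntry e2;
        e2.v = f[pq_];
        e2.ord = ord++;
        e2.idx = pq_;
        pq.push(e2);
      }
    }
  }
  for (int i = 0; i < nr * nc; ++i)
    if (lab[i] < 0) lab[i] = 0;
  return lab;
}

// Guo-Hall thinning to a 1-px skeleton; preserves 8-connectivity of the
// foreground and keeps the skeleton inside the input mask.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix input) {
  const int nr = input.nrow(), nc = input.ncol();
  std::vector<char> img((size_t)nr * nc);
  for (int i = 0; i < nr * nc; ++i) img[i] = input[i] ? 1 : 0;
  std::vector<int> del, work, keep;
  std::vector<char> inwork((size_t)nr * nc, 0);
  // neighbours outside the frame count as background
  #define PX(r, c) (((r) < 0 || (r) >= nr || (c) < 0 || (c) >= nc) ? 0 : \
                    img[(size_t)(c) * nr + (r)])
  // only pixels touching background are deletion candidates; seed the
  // worklist with the boundary and grow it around deletions
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!img[(size_t)c * nr + r]) continue;
      if (!(PX(r - 1, c) && PX(r, c + 1) && PX(r + 1, c) && PX(r, c - 1))) {
        work.push_back(c * nr + r);
        inwork[(size_t)c * nr + r] = 1;
      }
    }
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      del.clear();
      for (size_t wi = 0; wi < work.size(); ++wi) {
        int p = work[wi];
        if (!img[p]) continue;
        int r = p % nr, c = p / nr;
        int p2 = PX(r - 1, c), p4 = PX(r, c + 1), p6 = PX(r + 1, c),
            p8 = PX(r, c - 1);
        if (p2 && p4 && p6 && p8) continue;  // interior: C == 0
        int p3 = PX(r - 1, c + 1), p5 = PX(r + 1, c + 1),
            p7 = PX(r + 1, c - 1), p9 = PX(r - 1, c - 1);
        int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
        int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
        int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
        int N = N1 < N2 ? N1 : N2;
        int m = (iter == 0) ? ((p6 | p7 | (!p9)) & p8)
                            : ((p2 | p3 | (!p5)) & p4);
        if (C == 1 && N >= 2 && N <= 3 && m == 0)
          del.push_back(p);
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i) img[del[i]] = 0;
      for (size_t i = 0; i < del.size(); ++i) {
        int r = del[i] % nr, c = del[i] / nr;
        for (int k = 0; k < 8; ++k) {
          int qr = r + DR8[k], qc = c + DC8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          int q = qc * nr + qr;
          if (img[q] && !inwork[q]) {
            inwork[q] = 1;
            work.push_back(q);
          }
        }
      }
    }
    // compact: drop deleted pixels from the worklist
    keep.clear();
    for (size_t wi = 0; wi < work.size(); ++wi) {
      if (img[work[wi]]) keep.push_back(work[wi]);
      else inwork[work[wi]] = 0;
    }
    work.swap(keep);
  }
  #undef PX
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr * nc; ++i) out[i] = img[i] != 0;
  return out;
}

// Separable correlation with a (symmetric) 1-D kernel, rows then columns,
// replicate border.
// [[Rcpp::export]]
NumericMatrix cpp_convolve_sep(NumericMatrix img, NumericVector kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int h = kl / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int k = -h; k <= h; ++k)
        acc += kernel[k + h] * img(clampi(r + k, 0, nr - 1), c);
      tmp(r, c) = acc;
    }
  }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int k = -h; k <= h; ++k)
        acc += kernel[k + h] * tmp(r, clampi(c + k, 0, nc - 1));
      out(r, c) = acc;
    }
  }
  return out;
}

// 1-D squared-distance lower envelope (Felzenszwalb & Huttenlocher)
static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n,
                   std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e20;
  z[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e20;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// binary dilation by a Euclidean disk via the exact squared distance
// transform: a pixel is set iff its distance to the foreground is <= radius
// [[Rcpp::export]]
LogicalMatrix cpp_binary_dilate_disk(LogicalMatrix mask, double radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int nmax = std::max(nr, nc);
  std::vector<double> g((size_t)nr * nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int c = 0; c < nc; ++c) {            // column pass
    for (int r = 0; r < nr; ++r)
      f[r] = mask[(size_t)c * nr + r] ? 0.0 : 1e20;
    edt_1d(f, d, nr, v, z);
    for (int r = 0; r < nr; ++r) g[(size_t)c * nr + r] = d[r];
  }
  LogicalMatrix out(nr, nc);
  const double r2 = radius * radius;
  for (int r = 0; r < nr; ++r) {            // row pass
    for (int c = 0; c < nc; ++c) f[c] = g[(size_t)c * nr + r];
    edt_1d(f, d, nc, v, z);
    for (int c = 0; c < nc; ++c)
      out[(size_t)c * nr + r] = d[c] <= r2;
  }
  return out;
}

// one box-mean pass (halfwidth h) along columns then rows via prefix sums;
// replicate border handled by counting clipped window cells at the edge value
static void box_pass(NumericMatrix& img, int h, std::vector<double>& S) {
  const int nr = img.nrow(), nc = img.ncol();
  const double wlen = 2.0 * h + 1.0;
  // columns
  if ((int)S.size() < std::max(nr, nc) + 1) S.resize(std::max(nr, nc) + 1);
  for (int c = 0; c < nc; ++c) {
    double* p = &img[(size_t)c * nr];
    S[0] = 0.0;
    for (int i = 0; i < nr; ++i) S[i + 1] = S[i] + p[i];
    double lo = p[0], hi = p[nr - 1];
    for (int i = 0; i < nr; ++i) {
      int a = i - h, b = i + h;
      double acc = 0.0;
      if (a < 0) { acc += (-a) * lo; a = 0; }
      if (b > nr - 1) { acc += (b - nr + 1) * hi; b = nr - 1; }
      acc += S[b + 1] - S[a];
      p[i] = acc / wlen;
    }
  }
  // rows: sliding sum over a window of columns, kept column-contiguous
  std::vector<double> acc(nr);
  std::vector<double> res((size_t)nr * nc);
  for (int i = 0; i < nr; ++i) acc[i] = 0.0;
  for (int cc = -h; cc <= h; ++cc) {
    const double* p = &img[(size_t)clampi(cc, 0, nc - 1) * nr];
    for (int i = 0; i < nr; ++i) acc[i] += p[i];
  }
  for (int c = 0; c < nc; ++c) {
    double* rp = &res[(size_t)c * nr];
    for (int i = 0; i < nr; ++i) rp[i] = acc[i] / wlen;
    const double* addp = &img[(size_t)clampi(c + h + 1, 0, nc - 1) * nr];
    const double* subp = &img[(size_t)clampi(c - h, 0, nc - 1) * nr];
    for (int i = 0; i < nr; ++i) acc[i] += addp[i] - subp[i];
  }
  std::copy(res.begin(), res.end(), img.begin());
}

// three-pass box cascade approximating a Gaussian of the given sigma
// (O(1) per pixel per pass, independent of sigma)
// [[Rcpp::export]]
NumericMatrix cpp_box_gauss(NumericMatrix img, double sigma) {
  NumericMatrix out = clone(img);
  if (sigma <= 0) return out;
  const int n = 3;
  double wIdeal = std::sqrt(12.0 * sigma * sigma / n + 1.0);
  int wl = (int)std::floor(wIdeal);
  if (wl % 2 == 0) --wl;
  if (wl < 1) wl = 1;
  int wu = wl + 2;
  double mIdeal = (12.0 * sigma * sigma - n * wl * wl - 4.0 * n * wl - 3.0 * n) /
                  (-4.0 * wl - 4.0);
  int m = (int)std::floor(mIdeal + 0.5);
  if (m < 0) m = 0;
  if (m > n) m = n;
  std::vector<double> scratch;
  for (int i = 0; i < n; ++i) {
    int w = (i < m) ? wl : wu;
    int h = (w - 1) / 2;
    if (h > 0) box_pass(out, h, scratch);
  }
  return out;
}

// Sobel derivatives, replicate border. gx = d/dx (columns), gy = d/dy (rows);
// the gradient points from dark toward bright.
// [[Rcpp::export]]
List cpp_sobel(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix gx(nr, nc), gy(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int rm = clampi(r - 1, 0, nr - 1), rp = clampi(r + 1, 0, nr - 1);
      int cm = clampi(c - 1, 0, nc - 1), cp = clampi(c + 1, 0, nc - 1);
      gx(r, c) = (img(rm, cp) + 2.0 * img(r, cp) + img(rp, cp)) -
                 (img(rm, cm) + 2.0 * img(r, cm) + img(rp, cm));
      gy(r, c) = (img(rp, cm) + 2.0 * img(rp, c) + img(rp, cp)) -
                 (img(rm, cm) + 2.0 * img(rm, c) + img(rm, cp));
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}
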