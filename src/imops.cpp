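// Low-level raster kernels: separable convolution, disc morphology,
// CLAHE, connected components, thinning, multi-source flood fill.
// Images are numeric matrices (rows = y, columns = x), column-major as in R.
#include <RcppArmadillo.h>
#include <deque>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric boundary handling without repeating the edge sample
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_sep_conv(const NumericMatrix& img,
                           const NumericVector& krow,
                           const NumericVector& kcol) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hr = (krow.size() - 1) / 2, hc = (kcol.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass (along rows)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int k = -hr; k <= hr; ++k)
        s += krow[k + hr] * img(reflect_idx(r + k, nr), c);
      tmp(r, c) = s;
    }
  // horizontal pass (along columns)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int k = -hc; k <= hc; ++k)
        s += kcol[k + hc] * tmp(r, reflect_idx(c + k, nc));
      out(r, c) = s;
    }
  return out;
}

// sliding extreme along each matrix row, window [c-w, c+w], out-of-range ignored
static void sliding_row_extreme(const NumericMatrix& img, int w, bool take_min,
                                NumericMatrix& out) {
  const int nr = img.nrow(), nc = img.ncol();
  for (int r = 0; r < nr; ++r) {
    std::deque<int> dq; // monotonic deque of column indices
    int head = 0;       // next column to push
    for (int c = 0; c < nc; ++c) {
      const int hi = std::min(nc - 1, c + w);
      for (; head <= hi; ++head) {
        const double v = img(r, head);
        while (!dq.empty() &&
               (take_min ? img(r, dq.back()) >= v : img(r, dq.back()) <= v))
          dq.pop_back();
        dq.push_back(head);
      }
      while (dq.front() < c - w) dq.pop_front();
      out(r, c) = img(r, dq.front());
    }
  }
}

// grayscale erosion (take_min) / dilation over a disc of (possibly fractional)
// radius; SE = {offsets with euclidean norm <= radius}; borders handled by
// restricting the SE to the image domain.
static NumericMatrix disc_extreme(const NumericMatrix& img, double radius,
                                  bool take_min) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> halfw(2 * r + 1);
  std::vector<int> widths; // distinct halfwidths
  for (int dr = -r; dr <= r; ++dr) {
    int w = (int)std::floor(std::sqrt(radius * radius - (double)dr * dr) + 1e-9);
    halfw[dr + r] = w;
    if (std::find(widths.begin(), widths.end(), w) == widths.end())
      widths.push_back(w);
  }
  // horizontal sliding extreme per distinct halfwidth
  std::vector<NumericMatrix> H(widths.size());
  for (size_t i = 0; i < widths.size(); ++i) {
    H[i] = NumericMatrix(nr, nc);
    sliding_row_extreme(img, widths[i], take_min, H[i]);
  }
  std::vector<int> widx(2 * r + 1);
  for (int dr = -r; dr <= r; ++dr)
    widx[dr + r] = (int)(std::find(widths.begin(), widths.end(), halfw[dr + r]) -
                         widths.begin());
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int rr = 0; rr < nr; ++rr) {
      double best = take_min ? R_PosInf : R_NegInf;
      for (int dr = -r; dr <= r; ++dr) {
        const int r2 = rr + dr;
        if (r2 < 0 || r2 >= nr) continue;
        const double v = H[widx[dr + r]](r2, c);
        if (take_min ? v < best : v > best) best = v;
      }
      out(rr, c) = best;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_disc_erode(const NumericMatrix& img, double radius) {
  return disc_extreme(img, radius, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_disc_dilate(const NumericMatrix& img, double radius) {
  return disc_extreme(img, radius, false);
}

// local mean over a disc neighbourhood (restricted to the image domain)
// [[Rcpp::export]]
NumericMatrix cpp_disc_mean(const NumericMatrix& img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::floor(radius);
  // row-wise prefix sums
  NumericMatrix ps(nr, nc + 1);
  for (int rr = 0; rr < nr; ++rr)
    for (int c = 0; c < nc; ++c) ps(rr, c + 1) = ps(rr, c) + img(rr, c);
  std::vector<int> halfw(2 * r + 1);
  for (int dr = -r; dr <= r; ++dr)
    halfw[dr + r] =
        (int)std::floor(std::sqrt(radius * radius - (double)dr * dr) + 1e-9);
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int rr = 0; rr < nr; ++rr) {
      double s = 0.0;
      long cnt = 0;
      for (int dr = -r; dr <= r; ++dr) {
        const int r2 = rr + dr;
        if (r2 < 0 || r2 >= nr) continue;
        const int w = halfw[dr + r];
        const int c0 = std::max(0, c - w), c1 = std::min(nc - 1, c + w);
        s += ps(r2, c1 + 1) - ps(r2, c0);
        cnt += c1 - c0 + 1;
      }
      out(rr, c) = s / (double)cnt;
    }
  return out;
}

// Contrast limited adaptive histogram equalization over a tile grid with
// bilinear interpolation between tile mappings. Values are assumed in [0,1].
// A tile with zero intensity range maps identically (flat regions untouched).
// [[Rcpp::export]]
NumericMatrix cpp_clahe(const NumericMatrix& img, int ntiles, double clip_limit,
                        int nbins) {
  const int nr = img.nrow(), nc = img.ncol();
  const int tr = std::max(1, std::min(ntiles, nr));
  const int tc = std::max(1, std::min(ntiles, nc));
  std::vector<std::vector<double>> lut(tr * tc,
                                       std::vector<double>(nbins, 0.0));
  std::vector<bool> identity(tr * tc, false);
  std::vector<double> center_r(tr), center_c(tc);
  for (int ti = 0; ti < tr; ++ti) {
    const int r0 = (int)((double)ti * nr / tr);
    const int r1 = (int)((double)(ti + 1) * nr / tr);
    center_r[ti] = 0.5 * (r0 + r1 - 1);
    for (int tj = 0; tj < tc; ++tj) {
      const int c0 = (int)((double)tj * nc / tc);
      const int c1 = (int)((double)(tj + 1) * nc / tc);
      if (ti == 0) {} // centers per column computed below once
      std::vector<double> hist(nbins, 0.0);
      double vmin = R_PosInf, vmax = R_NegInf;
      long n = 0;
      for (int c = c0; c < c1; ++c)
        for (int r = r0; r < r1; ++r) {
          double v = img(r, c);
          if (v < vmin) vmin = v;
          if (v > vmax) vmax = v;
          int b = (int)(v * (nbins - 1) + 0.5);
          b = std::max(0, std::min(nbins - 1, b));
          hist[b] += 1.0;
          ++n;
        }
      const int t = ti * tc + tj;
      if (vmax - vmin <= 0.0 || n == 0) {
        identity[t] = true;
        continue;
      }
      // clip and redistribute
      const double limit =
          std::max(1.0, clip_limit * (double)n / (double)nbins);
      double excess = 0.0;
      for (int b = 0; b < nbins; ++b)
        if (hist[b] > limit) {
          excess += hist[b] - limit;
          hist[b] = limit;
        }
      const double add = excess / nbins;
      for (int b = 0; b < nbins; ++b) hist[b] += add;
      double cum = 0.0;
      for (int b = 0; b < nbins; ++b) {
        cum += hist[b];
        lut[t][b] = cum / (double)n;
      }
    }
  }
  for (int tj = 0; tj < tc; ++tj) {
    const int c0 = (int)((double)tj * nc / tc);
    const int c1 = (int)((double)(tj + 1) * nc / tc);
    center_c[tj] = 0.5 * (c0 + c1 - 1);
  }
  auto apply_tile = [&](int t, double v, int b) -> double {
    return identity[t] ? v : lut[t][b];
  };
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    // horizontal tile pair and weight
    int j0 = 0;
    while (j0 + 1 < tc && center_c[j0 + 1] <= c) ++j0;
    int j1 = std::min(tc - 1, j0 + 1);
    double wc = 0.0;
    if (j1 > j0 && c >= center_c[j0])
      wc = (c - center_c[j0]) / (center_c[j1] - center_c[j0]);
    if (c < center_c[0]) { j0 = j1 = 0; wc = 0.0; }
    if (c > center_c[tc - 1]) { j0 = j1 = tc - 1; wc = 0.0; }
    for (int r = 0; r < nr; ++r) {
      int i0 = 0;
      while (i0 + 1 < tr && center_r[i0 + 1] <= r) ++i0;
      int i1 = std::min(tr - 1, i0 + 1);
      double wr = 0.0;
      if (i1 > i0 && r >= center_r[i0])
        wr = (r - center_r[i0]) / (center_r[i1] - center_r[i0]);
      if (r < center_r[0]) { i0 = i1 = 0; wr = 0.0; }
      if (r > center_r[tr - 1]) { i0 = i1 = tr - 1; wr = 0.0; }
      const double v = std::max(0.0, std::min(1.0, img(r, c)));
      int b = (int)(v * (nbins - 1) + 0.5);
      b = std::max(0, std::min(nbins - 1, b));
      const double v00 = apply_tile(i0 * tc + j0, v, b);
      const double v01 = apply_tile(i0 * tc + j1, v, b);
      const double v10 = apply_tile(i1 * tc + j0, v, b);
      const double v11 = apply_tile(i1 * tc + j1, v, b);
      out(r, c) = (1 - wr) * ((1 - wc) * v00 + wc * v01) +
                  wr * ((1 - wc) * v10 + wc * v11);
    }
  }
  return out;
}

// 8- or 4-connected component labelling; labels consecutive from 1 in
// column-major discovery order (deterministic).
// [[Rcpp::export]]
IntegerMatrix cpp_label(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack_r, stack_c;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack_r.clear(); stack_c.clear();
      stack_r.push_back(r); stack_c.push_back(c);
      lab(r, c) = next;
      while (!stack_r.empty()) {
        const int rr = stack_r.back(); stack_r.pop_back();
        const int cc = stack_c.back(); stack_c.pop_back();
        for (int k = 0; k < nn; ++k) {
          const int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack_r.push_back(r2); stack_c.push_back(c2);
          }
        }
      }
    }
  return lab;
}

static inline int px(const IntegerMatrix& m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c) != 0 ? 1 : 0;
}

// Zhang-Suen thinning plus a cleanup pass that removes residual pixels of
// 2x2 blocks when deletion preserves local 8-connectivity.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix m = clone(mask);
  for (int i = 0; i < nr * nc; ++i) m[i] = m[i] != 0 ? 1 : 0;
  bool changed = true;
  std::vector<std::pair<int,int>> del;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
          if (m(r, c) == 0) continue;
          const int p2 = px(m, r - 1, c),     p3 = px(m, r - 1, c + 1);
          const int p4 = px(m, r, c + 1),     p5 = px(m, r + 1, c + 1);
          const int p6 = px(m, r + 1, c),     p7 = px(m, r + 1, c - 1);
          const int p8 = px(m, r, c - 1),     p9 = px(m, r - 1, c - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int k = 0; k < 8; ++k)
            if (seq[k] == 0 && seq[k + 1] == 1) ++A;
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back({r, c});
        }
      if (!del.empty()) changed = true;
      for (auto& rc : del) m(rc.first, rc.second) = 0;
    }
  }
  // cleanup of surviving 2x2 blocks
  for (int c = 0; c < nc - 1; ++c)
    for (int r = 0; r < nr - 1; ++r) {
      if (m(r, c) && m(r + 1, c) && m(r, c + 1) && m(r + 1, c + 1)) {
        // try removing each of the four in fixed order, keep simple pixels out
        const int cand_r[4] = {r, r, r + 1, r + 1};
        const int cand_c[4] = {c, c + 1, c, c + 1};
        for (int k = 0; k < 4; ++k) {
          const int rr = cand_r[k], cc = cand_c[k];
          const int p2 = px(m, rr - 1, cc),     p3 = px(m, rr - 1, cc + 1);
          const int p4 = px(m, rr, cc + 1),     p5 = px(m, rr + 1, cc + 1);
          const int p6 = px(m, rr + 1, cc),     p7 = px(m, rr + 1, cc - 1);
          const int p8 = px(m, rr, cc - 1),     p9 = px(m, rr - 1, cc - 1);
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int q = 0; q < 8; ++q)
            if (seq[q] == 0 && seq[q + 1] == 1) ++A;
          if (A == 1) { m(rr, cc) = 0; break; }
        }
      }
    }
  return m;
}

// Parallel (level-synchronous) multi-source flood fill restricted to mask.
// seeds: 0 = unseeded, >0 = label. Ties at equal chessboard geodesic distance
// go to the lowest label. Unreached foreground keeps label 0.
// [[Rcpp::export]]
IntegerMatrix cpp_floodfill_multi(const IntegerMatrix& mask,
                                  const IntegerMatrix& seeds) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int>> cur, nxt;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c) != 0) {
        lab(r, c) = seeds(r, c);
        cur.push_back({r, c});
      }
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  IntegerMatrix pending(nr, nc);
  while (!cur.empty()) {
    nxt.clear();
    for (auto& rc : cur) {
      const int l = lab(rc.first, rc.second);
      for (int k = 0; k < 8; ++k) {
        const int r2 = rc.first + dr8[k], c2 = rc.second + dc8[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (mask(r2, c2) == 0 || lab(r2, c2) != 0) continue;
        if (pending(r2, c2) == 0) {
          pending(r2, c2) = l;
          nxt.push_back({r2, c2});
        } else if (l < pending(r2, c2)) {
          pending(r2, c2) = l;
        }
      }
    }
    for (auto& rc : nxt) {
      lab(rc.first, rc.second) = pending(rc.first, rc.second);
      pending(rc.first, rc.second) = 0;
    }
    cur.swap(nxt);
  }
  return lab;
}

// stamp a thick line (disc brush) between two pixels into a copy of mask
// [[Rcpp::export]]
IntegerMatrix cpp_draw_line(const IntegerMatrix& mask, int r0, int c0, int r1,
                            int c1, double halfwidth) {
  IntegerMatrix m = clone(mask);
  const int nr = m.nrow(), nc = m.ncol();
  const int hw = (int)std::ceil(halfwidth);
  const double steps = std::max(std::abs(r1 - r0), std::abs(c1 - c0));
  const int n = (int)steps + 1;
  for (int i = 0; i < n; ++i) {
    const double t = (n == 1) ? 0.0 : (double)i / (double)(n - 1);
    const int r = (int)std::round(r0 + t * (r1 - r0));
    const int c = (int)std::round(c0 + t * (c1 - c0));
    for (int dr = -hw; dr <= hw; ++dr)
      for (int dc = -hw; dc <= hw; ++dc) {
        if (dr * dr + dc * dc > halfwidth * halfwidth + 1e-9) continue;
        const int r2 = r + dr, c2 = c + dc;
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        m(r2, c2) = 1;
      }
  }
  return m;
}

// neighbour count (8-connectivity) for every foreground pixel of a mask
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_count(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) { out(r, c) = NA_INTEGER; continue; }
      int s = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          s += px(mask, r + dr, c + dc);
        }
      out(r, c) = s;
    }
  return out;
}

// skeleton polyline length: half the summed step lengths between 8-adjacent
// skeleton pixels (1 for axial, sqrt(2) for diagonal neighbours)
// [[Rcpp::export]]
double cpp_skeleton_length(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  double total = 0.0;
  const double sq2 = std::sqrt(2.0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) continue;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          if (px(mask, r + dr, c + dc))
            total += (dr != 0 && dc != 0) ? sq2 : 1.0;
        }
    }
  return total / 2.0;
}
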