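#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Rasterized Voronoi assignment: every pixel center (x = col-1, y = row-1,
// 0-based) is assigned to its nearest seed (Euclidean; ties -> lowest seed
// index). Seeds are bucketed on a coarse grid and searched in expanding
// Chebyshev rings with a distance bound, so cost is ~O(width*height).

// [[Rcpp::export]]
IntegerMatrix cpp_voronoi_labels(NumericVector sx, NumericVector sy, int width,
                                 int height) {
  int n = sx.size();
  if (n < 1) stop("need at least one seed");
  double bs = std::max(2.0, std::sqrt((double)width * height / n));
  int nbx = std::max(1, (int)std::ceil(width / bs));
  int nby = std::max(1, (int)std::ceil(height / bs));
  std::vector<std::vector<int>> bucket((size_t)nbx * nby);
  for (int i = 0; i < n; ++i) {
    int bx = std::min(nbx - 1, std::max(0, (int)(sx[i] / bs)));
    int by = std::min(nby - 1, std::max(0, (int)(sy[i] / bs)));
    bucket[(size_t)by * nbx + bx].push_back(i);
  }
  int maxring = nbx + nby + 2;
  IntegerMatrix lab(height, width);
  for (int py = 0; py < height; ++py) {
    int by0 = std::min(nby - 1, std::max(0, (int)(py / bs)));
    for (int px = 0; px < width; ++px) {
      int bx0 = std::min(nbx - 1, std::max(0, (int)(px / bs)));
      int best = -1;
      double bestd = R_PosInf;
      for (int r = 0; r <= maxring; ++r) {
        if (best >= 0) {
          double lb = (r - 1) * bs; // min distance to any seed in ring r
          if (lb > 0 && lb * lb > bestd) break;
        }
        int xlo = bx0 - r, xhi = bx0 + r, ylo = by0 - r, yhi = by0 + r;
        for (int by = std::max(0, ylo); by <= std::min(nby - 1, yhi); ++by) {
          bool edge_row = (by == ylo || by == yhi);
          for (int bx = std::max(0, xlo); bx <= std::min(nbx - 1, xhi); ++bx) {
            if (!edge_row && bx != xlo && bx != xhi) continue;
            for (int i : bucket[(size_t)by * nbx + bx]) {
              double dx = sx[i] - px, dy = sy[i] - py;
              double d = dx * dx + dy * dy;
              if (d < bestd || (d == bestd && i < best)) {
                bestd = d;
                best = i;
              }
            }
          }
        }
      }
      lab(py, px) = best + 1;
    }
  }
  return lab;
}

// Label pairs within `radius` (Euclidean, pixel centers): the dilation-
// overlap contact relation. Returns a 2-column matrix of unique pairs
// (small label first).
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(IntegerMatrix lab, double radius) {
  int h = lab.nrow(), w = lab.ncol();
  int r = (int)std::ceil(radius);
  std::vector<std::pair<int, int>> offs;
  for (int dx = 0; dx <= r; ++dx)
    for (int dy = -r; dy <= r; ++dy)
      if (dx * dx + dy * dy <= radius * radius && (dx > 0 || dy > 0))
        offs.push_back({dx, dy});
  std::vector<uint64_t> pairs;
  for (auto &o : offs) {
    int dx = o.first, dy = o.second;
    int y0 = std::max(0, -dy), y1 = std::min(h, h - dy);
    for (int py = y0; py < y1; ++py)
      for (int px = 0; px < w - dx; ++px) {
        int a = lab(py, px), b = lab(py + dy, px + dx);
        if (a > 0 && b > 0 && a != b) {
          if (a > b) std::swap(a, b);
          pairs.push_back((uint64_t(a) << 32) | uint64_t(b));
        }
      }
  }
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  IntegerMatrix out(pairs.size(), 2);
  for (size_t i = 0; i < pairs.size(); ++i) {
    out(i, 0) = (int)(pairs[i] >> 32);
    out(i, 1) = (int)(pairs[i] & 0xffffffffu);
  }
  return out;
}

// Per-label pixel count and centroid (0-based x = col-1, y = row-1).
// [[Rcpp::export]]
NumericMatrix cpp_region_stats(IntegerMatrix lab, int n) {
  NumericMatrix out(n, 3); // npix, sumx, sumy
  int h = lab.nrow(), w = lab.ncol();
  for (int px = 0; px < w; ++px)
    for (int py = 0; py < h; ++py) {
      int l = lab(py, px);
      if (l >= 1 && l <= n) {
        out(l - 1, 0) += 1;
        out(l - 1, 1) += px;
        out(l - 1, 2) += py;
      }
    }
  return out;
}

// CVT energy: sum of squared distances from each pixel center to the seed of
// its assigned region.
// [[Rcpp::export]]
double cpp_cvt_energy(IntegerMatrix lab, NumericVector sx, NumericVector sy) {
  int h = lab.nrow(), w = lab.ncol();
  double e = 0;
  for (int px = 0; px < w; ++px)
    for (int py = 0; py < h; ++py) {
      int l = lab(py, px);
      if (l >= 1 && l <= sx.size()) {
        double dx = sx[l - 1] - px, dy = sy[l - 1] - py;
        e += dx * dx + dy * dy;
      }
    }
  return e;
}

// Number of 8-connected components per positive label (index = label value).
// 8-connectivity tolerates the single-pixel diagonal steps that pixel-center
// assignment produces along oblique region boundaries.
// [[Rcpp::export]]
IntegerVector cpp_region_components(IntegerMatrix lab, int n) {
  int h = lab.nrow(), w = lab.ncol();
  std::vector<char> seen((size_t)h * w, 0);
  IntegerVector comp(n);
  std::vector<int> stack;
  for (int px = 0; px < w; ++px)
    for (int py = 0; py < h; ++py) {
      size_t id = (size_t)px * h + py;
      int l = lab(py, px);
      if (l < 1 || l > n || seen[id]) continue;
      comp[l - 1] += 1;
      seen[id] = 1;
      stack.clear();
      stack.push_back(px * h + py);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int cx = cur / h, cy = cur % h;
        const int dx[8] = {1, -1, 0, 0, 1, 1, -1, -1},
                  dy[8] = {0, 0, 1, -1, 1, -1, 1, -1};
        for (int d = 0; d < 8; ++d) {
          int nx = cx + dx[d], ny = cy + dy[d];
          if (nx < 0 || ny < 0 || nx >= w || ny >= h) continue;
          size_t nid = (size_t)nx * h + ny;
          if (!seen[nid] && lab(ny, nx) == l) {
            seen[nid] = 1;
            stack.push_back(nx * h + ny);
          }
        }
      }
    }
  return comp;
}
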