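#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Binary raster primitives used by the background-removal and segmentation
// paths. Masks are logical matrices (rows = y, cols = x). Connectivity is 8
// for foreground labelling (regions touching diagonally are one cell) and 4
// for hole filling, the usual complementary pairing.

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int dy8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[] = {-1, 0, 0, 1};
  const int dx4[] = {0, -1, 1, 0};
  const int* dy = (connectivity == 8) ? dy8 : dy4;
  const int* dx = (connectivity == 8) ? dx8 : dx4;
  const int nn = connectivity;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dy[k], cc = p.second + dx[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Disc structuring element: offsets with dx^2+dy^2 <= radius^2.
static std::vector<std::pair<int, int> > disc_offsets(int radius) {
  std::vector<std::pair<int, int> > off;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dx * dx + dy * dy <= radius * radius)
        off.push_back(std::make_pair(dy, dx));
  return off;
}

// [[Rcpp::export(name = ".dilate_cpp")]]
LogicalMatrix dilate_cpp(const LogicalMatrix& mask, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<std::pair<int, int> > off = disc_offsets(radius);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      for (size_t k = 0; k < off.size(); ++k) {
        int rr = r + off[k].first, cc = c + off[k].second;
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) out(rr, cc) = true;
      }
    }
  return out;
}

// [[Rcpp::export(name = ".erode_cpp")]]
LogicalMatrix erode_cpp(const LogicalMatrix& mask, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<std::pair<int, int> > off = disc_offsets(radius);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      bool all = mask(r, c);
      for (size_t k = 0; all && k < off.size(); ++k) {
        int rr = r + off[k].first, cc = c + off[k].second;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || !mask(rr, cc)) all = false;
      }
      out(r, c) = all;
    }
  return out;
}

// Fill holes: background pixels (4-connected) unreachable from the border
// become foreground. Used to solidify ring-like contours.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalMatrix fill_holes_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reach(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if ((r == 0 || r == nr - 1 || c == 0 || c == nc - 1) && !mask(r, c) && !reach(r, c)) {
        reach(r, c) = true;
        q.push(std::make_pair(r, c));
      }
    }
  }
  const int dy[] = {-1, 1, 0, 0}, dx[] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int k = 0; k < 4; ++k) {
      int rr = p.first + dy[k], cc = p.second + dx[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) && !reach(rr, cc)) {
        reach(rr, cc) = true;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) out(r, c) = mask(r, c) || !reach(r, c);
  return out;
}
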