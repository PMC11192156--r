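#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Binary-particle pixel geometry. Masks are 0/1 integer matrices in R's
// column-major layout; row index = y (downward), column index = x.
// Foreground connectivity is 8, background connectivity 4.

static inline bool fg_at(const IntegerMatrix& m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return false;
  return m(r, c) != 0;
}

//' @noRd
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int dr[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + nr * c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 8; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qc < 0 || qr >= nr || qc >= nc) continue;
          if (mask(qr, qc) != 0 && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + nr * qc);
          }
        }
      }
    }
  }
  return lab;
}

//' @noRd
// [[Rcpp::export(name = ".fill_holes")]]
IntegerMatrix fill_holes(const IntegerMatrix& mask) {
  // Background pixels 4-connected to the image border stay background;
  // every other zero pixel is an interior hole and becomes foreground.
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<uint8_t> outside((size_t)nr * nc, 0);
  std::vector<int> stack;
  auto push = [&](int r, int c) {
    size_t i = (size_t)r + (size_t)nr * c;
    if (mask(r, c) == 0 && !outside[i]) { outside[i] = 1; stack.push_back(r + nr * c); }
  };
  for (int c = 0; c < nc; ++c) { push(0, c); push(nr - 1, c); }
  for (int r = 0; r < nr; ++r) { push(r, 0); push(r, nc - 1); }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int pr = p % nr, pc = p / nr;
    for (int k = 0; k < 4; ++k) {
      int qr = pr + dr[k], qc = pc + dc[k];
      if (qr < 0 || qc < 0 || qr >= nr || qc >= nc) continue;
      push(qr, qc);
    }
  }
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = (mask(r, c) != 0 || !outside[(size_t)r + (size_t)nr * c]) ? 1 : 0;
  return out;
}

// Directed crack edge from corner (x, y) in direction d (0:+x, 1:+y, 2:-x,
// 3:-y) is valid when the pixel on its right is foreground and the pixel on
// its left is background; walking with foreground on the right yields a loop
// with positive shoelace area in (x, y-down) coordinates.
static inline bool edge_valid(const IntegerMatrix& m, int x, int y, int d) {
  switch (d) {
    case 0: return  fg_at(m, y,     x)     && !fg_at(m, y - 1, x);
    case 1: return  fg_at(m, y,     x - 1) && !fg_at(m, y,     x);
    case 2: return  fg_at(m, y - 1, x - 1) && !fg_at(m, y,     x - 1);
    default:return  fg_at(m, y - 1, x)     && !fg_at(m, y - 1, x - 1);
  }
}

//' @noRd
// [[Rcpp::export(name = ".trace_crack")]]
IntegerMatrix trace_crack(const IntegerMatrix& mask) {
  // Outer crack boundary of the (hole-filled) particle in `mask`.
  // Returns an M x 2 matrix of (x, y) corner coordinates, closed implicitly,
  // collinear runs collapsed. Saddle corners take the left turn so an
  // 8-connected component stays one (weakly simple) loop.
  const int nr = mask.nrow(), nc = mask.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c) != 0) { sr = r; sc = c; break; }
  if (sr < 0) stop("empty mask: no foreground pixel to trace");
  const int dx[4] = {1, 0, -1, 0};
  const int dy[4] = {0, 1, 0, -1};
  int x = sc, y = sr, d = 0;  // top-left corner of topmost-leftmost pixel
  std::vector<int> vx, vy;
  vx.push_back(x); vy.push_back(y);  // the walk both leaves and re-enters here with a turn
  const long guard = 4L * (nr + 2L) * (nc + 2L) + 8;
  long steps = 0;
  do {
    if (!edge_valid(mask, x, y, d)) stop("internal error: invalid crack edge");
    x += dx[d]; y += dy[d];
    // order: left turn, straight, right turn, back
    int cand[4] = {(d + 3) % 4, d, (d + 1) % 4, (d + 2) % 4};
    int nd = -1;
    for (int k = 0; k < 4; ++k)
      if (edge_valid(mask, x, y, cand[k])) { nd = cand[k]; break; }
    if (nd < 0) stop("internal error: crack walk dead end");
    if (nd != d && !(x == sc && y == sr)) { vx.push_back(x); vy.push_back(y); }
    d = nd;
    if (++steps > guard) stop("internal error: crack walk did not close");
  } while (!(x == sc && y == sr));
  size_t n = vx.size();
  IntegerMatrix out(n, 2);
  for (size_t i = 0; i < n; ++i) { out(i, 0) = vx[i]; out(i, 1) = vy[i]; }
  return out;
}
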