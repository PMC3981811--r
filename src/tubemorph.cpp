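#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 8-neighbour offsets, clockwise from East:
// x1..x8 = E, NE, N, NW, W, SW, S, SE (row decreases upward)
static const int NBR[8][2] = {
  {0, 1}, {-1, 1}, {-1, 0}, {-1, -1}, {0, -1}, {1, -1}, {1, 0}, {1, 1}
};

static inline bool at(const std::vector<uint8_t>& m, int nr, int nc, int r, int c) {
  if (r < 0 || r >= nr || c < 0 || c >= nc) return false;
  return m[(size_t)c * nr + r] != 0;
}

// Hilditch crossing number for 8-connected foreground / 4-connected
// background. A foreground pixel is "simple" (its removal changes neither
// the component count nor the hole count) iff XH == 1.
static inline int crossing_number(const std::vector<uint8_t>& m, int nr, int nc,
                                  int r, int c) {
  int x[9];
  for (int k = 0; k < 8; ++k)
    x[k] = at(m, nr, nc, r + NBR[k][0], c + NBR[k][1]) ? 1 : 0;
  x[8] = x[0];
  int xh = 0;
  for (int k = 0; k < 4; ++k) {
    // odd-indexed neighbours are the 4-neighbours E, N, W, S
    if (x[2 * k] == 0 && (x[2 * k + 1] == 1 || x[2 * k + 2] == 1))
      ++xh;
  }
  return xh;
}

static inline int neighbour_count(const std::vector<uint8_t>& m, int nr, int nc,
                                  int r, int c) {
  int n = 0;
  for (int k = 0; k < 8; ++k)
    if (at(m, nr, nc, r + NBR[k][0], c + NBR[k][1])) ++n;
  return n;
}

// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
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
        for (int k = 0; k < 8; ++k) {
          if (connectivity == 4 && (k % 2) == 1) continue;
          int rr = p.first + NBR[k][0], cc = p.second + NBR[k][1];
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

// Topology-preserving thinning: sequentially delete simple, non-endpoint
// border pixels in four directional sub-iterations (N, S, E, W borders)
// until a full cycle removes nothing. Sequential deletion of simple points
// provably preserves the Euler characteristic (component and hole counts);
// endpoint preservation (>= 2 neighbours required) keeps line ends.
// [[Rcpp::export(name = ".thin_mask")]]
LogicalMatrix thin_mask(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<uint8_t> m((size_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      m[(size_t)c * nr + r] = mask(r, c) ? 1 : 0;

  // Border direction (N, S, W, E neighbour is bg) is checked against a
  // snapshot taken at sub-pass start, so each sub-pass peels at most one
  // pixel layer; the simplicity test runs on the current state, keeping
  // deletions sequential and topology-safe.
  static const int DIRS[4][2] = { {-1, 0}, {1, 0}, {0, -1}, {0, 1} };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      std::vector<uint8_t> snap(m);
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m[(size_t)c * nr + r]) continue;
          if (!snap[(size_t)c * nr + r]) continue;
          if (at(snap, nr, nc, r + DIRS[d][0], c + DIRS[d][1])) continue;
          int nb = neighbour_count(m, nr, nc, r, c);
          if (nb < 2 || nb > 6) continue;
          if (crossing_number(m, nr, nc, r, c) != 1) continue;
          m[(size_t)c * nr + r] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = m[(size_t)c * nr + r] != 0;
  return out;
}

// Spur clipping: from every endpoint (exactly one 8-neighbour) walk inward
// marking up to `clip` pixels, stopping early when the next pixel is a
// branch point (>= 3 neighbours). Finite clip: one simultaneous pass.
// Infinite clip: passes repeat until a fixed point, which annihilates
// branch-free components entirely while junction cores survive.
// [[Rcpp::export(name = ".clip_spurs")]]
LogicalMatrix clip_spurs_cpp(LogicalMatrix skel, double clip) {
  int nr = skel.nrow(), nc = skel.ncol();
  std::vector<uint8_t> m((size_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      m[(size_t)c * nr + r] = skel(r, c) ? 1 : 0;

  bool infinite = !R_finite(clip);
  bool again = true;
  while (again) {
    again = false;
    std::vector<uint8_t> mark((size_t)nr * nc, 0);
    bool any = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!m[(size_t)c * nr + r]) continue;
        if (neighbour_count(m, nr, nc, r, c) != 1) continue;
        // walk inward from the endpoint
        int pr = -2, pc = -2, cr = r, cc = c;
        double steps = 0;
        while (steps < clip) {
          mark[(size_t)cc * nr + cr] = 1;
          any = true;
          steps += 1;
          // unique next pixel: the neighbour that is not where we came from
          int nxr = -1, nxc = -1, found = 0;
          for (int k = 0; k < 8; ++k) {
            int rr = cr + NBR[k][0], ccx = cc + NBR[k][1];
            if (rr == pr && ccx == pc) continue;
            if (at(m, nr, nc, rr, ccx)) { nxr = rr; nxc = ccx; ++found; }
          }
          if (found != 1) break;                       // annihilated or odd join
          if (neighbour_count(m, nr, nc, nxr, nxc) >= 3) break;  // branch point
          pr = cr; pc = cc; cr = nxr; cc = nxc;
        }
      }
    }
    if (any) {
      for (size_t i = 0; i < m.size(); ++i)
        if (mark[i]) m[i] = 0;
      if (infinite) again = true;  // finite clip: single pass only
    }
  }

  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = m[(size_t)c * nr + r] != 0;
  return out;
}

// Non-maximum suppression for Canny: keep a pixel when its gradient
// magnitude is a local maximum along the (quantised) gradient direction.
// [[Rcpp::export(name = ".nms")]]
LogicalMatrix nms_cpp(NumericMatrix mag, NumericMatrix gr, NumericMatrix gc) {
  int nr = mag.nrow(), nc = mag.ncol();
  LogicalMatrix keep(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = mag(r, c);
      if (v <= 0) { keep(r, c) = false; continue; }
      double t = std::atan2(gr(r, c), gc(r, c));
      if (t < 0) t += M_PI;  // fold to [0, pi)
      int dr = (int)std::lround(std::sin(t));
      int dc = (int)std::lround(std::cos(t));
      double n1 = 0, n2 = 0;
      int r1 = r + dr, c1 = c + dc, r2 = r - dr, c2 = c - dc;
      if (r1 >= 0 && r1 < nr && c1 >= 0 && c1 < nc) n1 = mag(r1, c1);
      if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) n2 = mag(r2, c2);
      keep(r, c) = (v > n1 && v >= n2);
    }
  }
  return keep;
}

// Count of foreground 8-neighbours at every pixel (used for endpoint and
// branch-point classification).
// [[Rcpp::export(name = ".neighbour_counts")]]
IntegerMatrix neighbour_counts(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<uint8_t> m((size_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      m[(size_t)c * nr + r] = mask(r, c) ? 1 : 0;
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = neighbour_count(m, nr, nc, r, c);
  return out;
}
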