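#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen morphological thinning of a binary image.
// Input: integer matrix with 0 background / 1 foreground.
// Output: matrix of same shape containing the one-pixel-wide skeleton.
// The two sub-iterations are applied until no pixel changes; border pixels
// are treated as background neighbours.

static inline int px(const IntegerMatrix& m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c);
}

static inline bool zs_deletable(const IntegerMatrix& m, int r, int c, int step) {
  // neighbours P2..P9 clockwise starting north
  int p2 = px(m, r - 1, c),     p3 = px(m, r - 1, c + 1);
  int p4 = px(m, r, c + 1),     p5 = px(m, r + 1, c + 1);
  int p6 = px(m, r + 1, c),     p7 = px(m, r + 1, c - 1);
  int p8 = px(m, r, c - 1),     p9 = px(m, r - 1, c - 1);
  int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
  if (B < 2 || B > 6) return false;
  int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
          (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
          (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
          (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
  if (A != 1) return false;
  if (step == 0) return p2 * p4 * p6 == 0 && p4 * p6 * p8 == 0;
  return p2 * p4 * p8 == 0 && p2 * p6 * p8 == 0;
}

// [[Rcpp::export(name = ".thin_zhang_suen")]]
IntegerMatrix thin_zhang_suen(IntegerMatrix img, Rcpp::Nullable<IntegerMatrix> anchors = R_NilValue) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix m = clone(img);
  std::vector<char> keep(static_cast<size_t>(nr) * nc, 0);
  if (anchors.isNotNull()) {
    IntegerMatrix a(anchors);
    for (int i = 0; i < nr * nc; ++i) keep[i] = a[i] != 0;
  }
  // active set: foreground pixels that may currently be deletable (border
  // pixels); refreshed from the neighbourhood of each deletion so every
  // iteration touches only the eroding front, not the whole image.
  std::vector<int> active, next_active, kill;
  std::vector<char> in_active(static_cast<size_t>(nr) * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (m(r, c)) {
        int B = px(m, r - 1, c) + px(m, r - 1, c + 1) + px(m, r, c + 1) +
                px(m, r + 1, c + 1) + px(m, r + 1, c) + px(m, r + 1, c - 1) +
                px(m, r, c - 1) + px(m, r - 1, c - 1);
        if (B < 8) { active.push_back(r + nr * c); in_active[r + nr * c] = 1; }
      }
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (size_t i = 0; i < active.size(); ++i) {
        int idx = active[i];
        int r = idx % nr, c = idx / nr;
        if (m[idx] && !keep[idx] && zs_deletable(m, r, c, step)) kill.push_back(idx);
      }
      if (kill.empty()) continue;
      changed = true;
      next_active.clear();
      for (size_t i = 0; i < kill.size(); ++i) m[kill[i]] = 0;
      for (size_t i = 0; i < active.size(); ++i) in_active[active[i]] = 0;
      // survivors plus all foreground neighbours of deleted pixels
      for (size_t i = 0; i < active.size(); ++i) {
        int idx = active[i];
        if (m[idx] && !in_active[idx]) { next_active.push_back(idx); in_active[idx] = 1; }
      }
      for (size_t i = 0; i < kill.size(); ++i) {
        int r = kill[i] % nr, c = kill[i] / nr;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
            int j = rr + nr * cc;
            if (m[j] && !in_active[j]) { next_active.push_back(j); in_active[j] = 1; }
          }
      }
      active.swap(next_active);
    }
  }
  return m;
}

// Sequential simple-point removal: deletes, one at a time, every non-anchor
// pixel that is 8-simple (Yokoi connectivity number == 1, so removal keeps
// the foreground locally 8-connected) and not a path endpoint (>= 2
// neighbours). Collapses the two-pixel ribbons parallel thinning or anchor
// plateaus can leave -- including exact-diagonal ribbons, where the naive
// circular crossing number over-counts -- without changing topology.
// [[Rcpp::export(name = ".thin_sequential")]]
IntegerMatrix thin_sequential(IntegerMatrix img, Rcpp::Nullable<IntegerMatrix> anchors = R_NilValue) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix m = clone(img);
  std::vector<char> keep(static_cast<size_t>(nr) * nc, 0);
  if (anchors.isNotNull()) {
    IntegerMatrix a(anchors);
    for (int i = 0; i < nr * nc; ++i) keep[i] = a[i] != 0;
  }
  bool changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int idx = r + nr * c;
        if (!m[idx] || keep[idx]) continue;
        int p2 = px(m, r - 1, c),     p3 = px(m, r - 1, c + 1);
        int p4 = px(m, r, c + 1),     p5 = px(m, r + 1, c + 1);
        int p6 = px(m, r + 1, c),     p7 = px(m, r + 1, c - 1);
        int p8 = px(m, r, c - 1),     p9 = px(m, r - 1, c - 1);
        int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
        if (B < 2) continue;
        // Yokoi connectivity number for 8-connected foreground:
        // sum over 4-neighbours p_k (k = 2,4,6,8) of
        //   (1-p_k) - (1-p_k)(1-p_{k+1})(1-p_{k+2})
        int nc8 = ((1 - p2) - (1 - p2) * (1 - p3) * (1 - p4)) +
                  ((1 - p4) - (1 - p4) * (1 - p5) * (1 - p6)) +
                  ((1 - p6) - (1 - p6) * (1 - p7) * (1 - p8)) +
                  ((1 - p8) - (1 - p8) * (1 - p9) * (1 - p2));
        if (nc8 != 1) continue;
        m[idx] = 0;
        changed = true;
      }
  }
  return m;
}

// Count 8-connected neighbours of each foreground pixel.
// [[Rcpp::export(name = ".skeleton_degree")]]
IntegerMatrix skeleton_degree(IntegerMatrix skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  IntegerMatrix deg(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!skel(r, c)) { deg(r, c) = NA_INTEGER; continue; }
      int d = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          d += px(skel, r + dr, c + dc);
        }
      deg(r, c) = d;
    }
  return deg;
}
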