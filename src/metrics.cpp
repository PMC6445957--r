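#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

typedef std::vector<unsigned char> Mask;

inline int at(const Mask& m, int nr, int r, int c) { return m[r + c * nr]; }
inline void set(Mask& m, int nr, int r, int c, unsigned char v) {
  m[r + c * nr] = v;
}

Mask dilate3(const Mask& m, int nr, int nc) {
  Mask out(nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!at(m, nr, r, c)) continue;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) set(out, nr, rr, cc, 1);
        }
    }
  return out;
}

Mask erode3(const Mask& m, int nr, int nc) {
  Mask out(nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      bool all = true;
      for (int dc = -1; dc <= 1 && all; ++dc)
        for (int dr = -1; dr <= 1 && all; ++dr) {
          int rr = r + dr, cc = c + dc;
          // outside the image counts as background (padding with zeros)
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || !at(m, nr, rr, cc))
            all = false;
        }
      if (all) set(out, nr, r, c, 1);
    }
  return out;
}

// neighbors in the circular order P2..P9 used by Zhang-Suen
const int ZDR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
const int ZDC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// Zhang-Suen thinning to a 1-pixel-wide 8-connected skeleton.
Mask zhang_suen(Mask m, int nr, int nc) {
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
          if (!at(m, nr, r, c)) continue;
          int p[8];
          for (int k = 0; k < 8; ++k) {
            int rr = r + ZDR[k], cc = c + ZDC[k];
            p[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc)
                       ? at(m, nr, rr, cc) : 0;
          }
          int bsum = 0;
          for (int k = 0; k < 8; ++k) bsum += p[k];
          if (bsum < 2 || bsum > 6) continue;
          int a = 0;
          for (int k = 0; k < 8; ++k)
            if (!p[k] && p[(k + 1) % 8]) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // N*E*S
            if (p[2] * p[4] * p[6] != 0) continue;  // E*S*W
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // N*E*W
            if (p[0] * p[4] * p[6] != 0) continue;  // N*S*W
          }
          kill.push_back(r + c * nr);
        }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) m[kill[k]] = 0;
    }
  }
  return m;
}

int skel_neighbors(const Mask& m, int nr, int nc, int r, int c) {
  int n = 0;
  for (int k = 0; k < 8; ++k) {
    int rr = r + ZDR[k], cc = c + ZDC[k];
    if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && at(m, nr, rr, cc)) ++n;
  }
  return n;
}

}  // namespace

// Skeleton-based branch analysis of a binary occupancy mask:
//   optional 3x3 morphological closing (smoothing) -> thinning (Zhang-Suen)
//   -> junction pixels (skeleton pixels with > 2 skeleton neighbors) merged
//   into 8-connected junction clusters counted once -> total skeleton length
//   as the sum of pixel-pair edges (1 per orthogonal step, sqrt(2) per
//   diagonal step; diagonal edges that shortcut an existing orthogonal
//   connection are not double-counted). Lengths are in lattice units.
// [[Rcpp::export]]
List cpp_branch_analysis(IntegerMatrix mask, bool smooth) {
  const int nr = mask.nrow(), nc = mask.ncol();
  Mask m(nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c) != 0) set(m, nr, r, c, 1);

  if (smooth) m = erode3(dilate3(m, nr, nc), nr, nc);
  Mask skel = zhang_suen(m, nr, nc);

  // junction clusters
  std::vector<unsigned char> junc(nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (at(skel, nr, r, c) && skel_neighbors(skel, nr, nc, r, c) > 2)
        junc[r + c * nr] = 1;
  int n_clusters = 0;
  std::vector<int> stack;
  std::vector<unsigned char> seen(nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int idx = r + c * nr;
      if (!junc[idx] || seen[idx]) continue;
      ++n_clusters;
      stack.push_back(idx);
      seen[idx] = 1;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int cr = cur % nr, cc2 = cur / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = cr + ZDR[k], cc = cc2 + ZDC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int j = rr + cc * nr;
          if (junc[j] && !seen[j]) {
            seen[j] = 1;
            stack.push_back(j);
          }
        }
      }
    }

  // total length: each adjacent skeleton pixel pair counted once
  double length = 0.0;
  const double SQ2 = std::sqrt(2.0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!at(skel, nr, r, c)) continue;
      // orthogonal: east and south
      if (c + 1 < nc && at(skel, nr, r, c + 1)) length += 1.0;
      if (r + 1 < nr && at(skel, nr, r + 1, c)) length += 1.0;
      // diagonal: south-east and south-west, skipped when an orthogonal
      // two-step path through a shared neighbor already connects the pair
      if (r + 1 < nr && c + 1 < nc && at(skel, nr, r + 1, c + 1) &&
          !at(skel, nr, r, c + 1) && !at(skel, nr, r + 1, c))
        length += SQ2;
      if (r + 1 < nr && c - 1 >= 0 && at(skel, nr, r + 1, c - 1) &&
          !at(skel, nr, r, c - 1) && !at(skel, nr, r + 1, c))
        length += SQ2;
    }

  IntegerMatrix sk(nr, nc);
  int n_skel = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      sk(r, c) = at(skel, nr, r, c);
      n_skel += sk(r, c);
    }

  return List::create(_["branch_points"] = n_clusters,
                      _["length_sites"] = length,
                      _["n_skeleton_px"] = n_skel, _["skeleton"] = sk);
}
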