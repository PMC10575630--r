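// Binary thinning: parallel Zhang-Suen to near-convergence, then a
// sequential simple-point cleanup that removes the two-pixel diagonal
// staircases the parallel scheme leaves. Pixels are removed only when
// 8-simple (deletion preserves local 8-connectivity) and not endpoints.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// Ring order: N, NE, E, SE, S, SW, W, NW (dr, dc) with rows growing down.
const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// simple-point lookup over the 256 neighbor configurations
bool lut_ready = false;
bool simple_lut[256];

void build_lut() {
  for (int cfg = 0; cfg < 256; ++cfg) {
    int idx[8], n = 0;
    for (int k = 0; k < 8; ++k)
      if (cfg & (1 << k)) idx[n++] = k;
    if (n == 0) { simple_lut[cfg] = false; continue; }
    // union-find over foreground ring positions, 8-adjacency between
    // their pixel offsets
    int comp[8];
    for (int i = 0; i < n; ++i) comp[i] = i;
    bool changed = true;
    while (changed) {
      changed = false;
      for (int a = 0; a < n; ++a) {
        for (int b = 0; b < n; ++b) {
          int dr = DR[idx[a]] - DR[idx[b]], dc = DC[idx[a]] - DC[idx[b]];
          if ((a != b) && std::abs(dr) <= 1 && std::abs(dc) <= 1 &&
              comp[a] != comp[b]) {
            int old = comp[b];
            for (int t = 0; t < n; ++t)
              if (comp[t] == old) comp[t] = comp[a];
            changed = true;
          }
        }
      }
    }
    int ncomp = 0;
    for (int i = 0; i < n; ++i) {
      bool seen = false;
      for (int j = 0; j < i; ++j)
        if (comp[j] == comp[i]) { seen = true; break; }
      if (!seen) ++ncomp;
    }
    simple_lut[cfg] = (ncomp == 1);
  }
  lut_ready = true;
}

inline int at(const IntegerVector& m, int H, int r, int c) {
  return m[r + c * H];
}

} // namespace

// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  if (!lut_ready) build_lut();
  int H = mask.nrow(), W = mask.ncol();
  IntegerVector m(mask.begin(), mask.end());
  std::vector<int> del;
  del.reserve(1024);

  // parallel Zhang-Suen
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 1; sub <= 2; ++sub) {
      del.clear();
      for (int c = 1; c < W - 1; ++c) {
        for (int r = 1; r < H - 1; ++r) {
          int p = r + c * H;
          if (!m[p]) continue;
          int nb[8];
          int B = 0;
          for (int k = 0; k < 8; ++k) {
            nb[k] = at(m, H, r + DR[k], c + DC[k]);
            B += nb[k];
          }
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k)
            if (nb[k] == 0 && nb[(k + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          // nb: 0=N,1=NE,2=E,3=SE,4=S,5=SW,6=W,7=NW
          bool cond;
          if (sub == 1)
            cond = (nb[0] * nb[2] * nb[4] == 0) && (nb[2] * nb[4] * nb[6] == 0);
          else
            cond = (nb[0] * nb[2] * nb[6] == 0) && (nb[0] * nb[4] * nb[6] == 0);
          if (cond) del.push_back(p);
        }
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i) m[del[i]] = 0;
    }
  }

  // sequential simple-point cleanup
  changed = true;
  while (changed) {
    changed = false;
    for (int c = 1; c < W - 1; ++c) {
      for (int r = 1; r < H - 1; ++r) {
        int p = r + c * H;
        if (!m[p]) continue;
        int cfg = 0, B = 0;
        for (int k = 0; k < 8; ++k) {
          if (at(m, H, r + DR[k], c + DC[k])) { cfg |= (1 << k); ++B; }
        }
        if (B >= 2 && simple_lut[cfg]) {
          m[p] = 0;
          changed = true;
        }
      }
    }
  }

  IntegerMatrix out(H, W);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
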