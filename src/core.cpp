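#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Deterministic RNG independent of R's RNG state (xorshift64*).
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed * 2654435761ULL + 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s * 2685821657736338717ULL;
  }
  // uniform integer in [lo, hi]
  int uniform(int lo, int hi) {
    return lo + (int)(next() % (uint64_t)(hi - lo + 1));
  }
};

// Squared Euclidean distance between feature vectors of pixels p and q,
// with early exit once the partial sum exceeds `best`. When `perm` is
// non-null the target's components are read through the permutation
// (used to match against the horizontally mirrored patch).
static inline double featDist(const std::vector<float>& F, int d,
                              int p, int q, double best,
                              const int* perm = nullptr) {
  const float* a = &F[(size_t)p * d];
  const float* b = &F[(size_t)q * d];
  double acc = 0.0;
  if (perm) {
    for (int k = 0; k < d; ++k) {
      double diff = (double)a[k] - (double)b[perm[k]];
      acc += diff * diff;
      if (acc > best) return acc;
    }
  } else {
    for (int k = 0; k < d; ++k) {
      double diff = (double)a[k] - (double)b[k];
      acc += diff * diff;
      if (acc > best) return acc;
    }
  }
  return acc;
}

// Randomized nearest-neighbor-field search over a dense feature field.
// Offsets shorter than min_off (Euclidean) are inadmissible, as are
// targets outside the validity mask. Propagation passes the two causal
// neighbors' offsets plus mirror-adjusted variants (offset +/- 2 along the
// scan axis), which lets the field converge on mirrored and 180-rotated
// clones whose offsets vary linearly. Random search halves its window from
// max(rows, cols) down to 1.
// [[Rcpp::export]]
List pm_nnf(NumericVector feats, LogicalMatrix valid, int iters,
            int min_off, int seed, IntegerVector mirror_perm) {
  IntegerVector dims = feats.attr("dim");
  const int rows = dims[0], cols = dims[1], d = dims[2];
  const int n = rows * cols;
  const double min2 = (double)min_off * (double)min_off;
  const bool use_mirror = mirror_perm.size() == d;
  std::vector<int> perm(use_mirror ? d : 0);
  for (int k = 0; k < (int)perm.size(); ++k) perm[k] = mirror_perm[k];
  const int* permp = use_mirror ? perm.data() : nullptr;

  // repack feature-major for cache locality
  std::vector<float> F((size_t)n * d);
  for (int k = 0; k < d; ++k) {
    const double* src = &feats[(size_t)k * n];
    for (int p = 0; p < n; ++p) F[(size_t)p * d + k] = (float)src[p];
  }
  std::vector<char> V(n);
  for (int p = 0; p < n; ++p) V[p] = valid[p] ? 1 : 0;

  std::vector<int> DR(n, 0), DC(n, 0);
  std::vector<double> COST(n, R_PosInf);
  std::vector<char> OK(n, 0), MIR(n, 0);

  XRng rng((uint64_t)(uint32_t)seed);

  auto admissible = [&](int r, int c, int tr, int tc) -> bool {
    if (tr < 0 || tr >= rows || tc < 0 || tc >= cols) return false;
    if (!V[tr + rows * tc]) return false;
    double dr = tr - r, dc = tc - c;
    return dr * dr + dc * dc >= min2;
  };

  // seeded random initialization (with deterministic fallback scan)
  for (int c = 0; c < cols; ++c) for (int r = 0; r < rows; ++r) {
    int p = r + rows * c;
    if (!V[p]) continue;
    bool found = false;
    for (int t = 0; t < 64 && !found; ++t) {
      int tr = rng.uniform(0, rows - 1), tc = rng.uniform(0, cols - 1);
      if (admissible(r, c, tr, tc)) {
        DR[p] = tr - r; DC[p] = tc - c;
        COST[p] = featDist(F, d, p, tr + rows * tc, R_PosInf);
        OK[p] = 1; found = true;
      }
    }
    if (!found) {
      for (int tc = 0; tc < cols && !found; ++tc)
        for (int tr = 0; tr < rows && !found; ++tr)
          if (admissible(r, c, tr, tc)) {
            DR[p] = tr - r; DC[p] = tc - c;
            COST[p] = featDist(F, d, p, tr + rows * tc, R_PosInf);
            OK[p] = 1; found = true;
          }
    }
  }

  auto tryCand = [&](int r, int c, int p, int tr, int tc, int mir) {
    if (mir && !use_mirror) return;
    if (!admissible(r, c, tr, tc)) return;
    double cst = featDist(F, d, p, tr + rows * tc, COST[p],
                          mir ? permp : nullptr);
    if (cst < COST[p]) {
      COST[p] = cst; DR[p] = tr - r; DC[p] = tc - c; MIR[p] = (char)mir;
    }
  };

  const int wmax = std::max(rows, cols);
  for (int it = 1; it <= iters; ++it) {
    const bool fwd = (it % 2 == 1);
    const int s = fwd ? 1 : -1;
    const int r0 = fwd ? 0 : rows - 1, c0 = fwd ? 0 : cols - 1;
    for (int ci = 0; ci < cols; ++ci) {
      int c = c0 + s * ci;
      for (int ri = 0; ri < rows; ++ri) {
        int r = r0 + s * ri;
        int p = r + rows * c;
        if (!OK[p]) continue;
        // propagation from the causal horizontal neighbor
        int ch = c - s;
        if (ch >= 0 && ch < cols && OK[r + rows * ch]) {
          int q = r + rows * ch;
          tryCand(r, c, p, r + DR[q], c + DC[q], MIR[q]);
          // mirrored clones have offsets with slope -2 along columns
          tryCand(r, c, p, r + DR[q], c + DC[q] - 2 * s, MIR[q]);
        }
        // propagation from the causal vertical neighbor
        int rh = r - s;
        if (rh >= 0 && rh < rows && OK[rh + rows * c]) {
          int q = rh + rows * c;
          tryCand(r, c, p, r + DR[q], c + DC[q], MIR[q]);
          tryCand(r, c, p, r + DR[q] - 2 * s, c + DC[q], MIR[q]);
        }
        // anti-causal neighbors (their offsets stem from the previous
        // sweep); speeds up convergence on weakly coherent fields
        int ca = c + s;
        if (ca >= 0 && ca < cols && OK[r + rows * ca]) {
          int q = r + rows * ca;
          tryCand(r, c, p, r + DR[q], c + DC[q], MIR[q]);
        }
        int ra = r + s;
        if (ra >= 0 && ra < rows && OK[ra + rows * c]) {
          int q = ra + rows * c;
          tryCand(r, c, p, r + DR[q], c + DC[q], MIR[q]);
        }
        // shrinking random search around the current best target
        // (three samples per radius scale, plus one uniform restart)
        for (int w = wmax; w >= 1; w >>= 1) {
          for (int t = 0; t < 3; ++t) {
            int tr = r + DR[p] + rng.uniform(-w, w);
            int tc = c + DC[p] + rng.uniform(-w, w);
            tryCand(r, c, p, tr, tc, MIR[p]);
            if (use_mirror) tryCand(r, c, p, tr, tc, !MIR[p]);
          }
        }
        {
          int tr = rng.uniform(0, rows - 1), tc = rng.uniform(0, cols - 1);
          tryCand(r, c, p, tr, tc, 0);
          if (use_mirror) tryCand(r, c, p, tr, tc, 1);
        }
      }
    }
  }

  IntegerMatrix outDr(rows, cols), outDc(rows, cols);
  NumericMatrix outCost(rows, cols);
  LogicalMatrix outOk(rows, cols), outMir(rows, cols);
  for (int p = 0; p < n; ++p) {
    outDr[p] = DR[p]; outDc[p] = DC[p];
    outCost[p] = OK[p] ? COST[p] : NA_REAL;
    outOk[p] = OK[p] ? TRUE : FALSE;
    outMir[p] = MIR[p] ? TRUE : FALSE;
  }
  return List::create(_["dr"] = outDr, _["dc"] = outDc,
                      _["cost"] = outCost, _["valid"] = outOk,
                      _["mirrored"] = outMir);
}

// Median filtering of the offset field over kept pixels, followed by the
// dense-linear-fitting test: each kept pixel's (filtered) offset is
// compared against a local affine model fitted by least squares on its
// neighborhood; pixels whose squared residual exceeds `thresh` (or with
// fewer than `min_pts` kept neighbors) are dropped.
// [[Rcpp::export]]
List dlf_filter(IntegerMatrix dr, IntegerMatrix dc, LogicalMatrix keep,
                int median_win, double thresh, int min_pts) {
  const int rows = dr.nrow(), cols = dr.ncol();
  const int hm = median_win / 2;
  IntegerMatrix fdr(rows, cols), fdc(rows, cols);
  LogicalMatrix out(rows, cols);

  // pass 1: median filter over kept neighbors (window median_win)
  std::vector<int> bufR, bufC;
  bufR.reserve((2 * hm + 1) * (2 * hm + 1));
  bufC.reserve((2 * hm + 1) * (2 * hm + 1));
  for (int c = 0; c < cols; ++c) for (int r = 0; r < rows; ++r) {
    if (!keep(r, c)) continue;
    bufR.clear(); bufC.clear();
    for (int cc = std::max(0, c - hm); cc <= std::min(cols - 1, c + hm); ++cc)
      for (int rr = std::max(0, r - hm); rr <= std::min(rows - 1, r + hm); ++rr)
        if (keep(rr, cc)) { bufR.push_back(dr(rr, cc)); bufC.push_back(dc(rr, cc)); }
    size_t mid = bufR.size() / 2;
    std::nth_element(bufR.begin(), bufR.begin() + mid, bufR.end());
    std::nth_element(bufC.begin(), bufC.begin() + mid, bufC.end());
    fdr(r, c) = bufR[mid];
    fdc(r, c) = bufC[mid];
  }

  // pass 2: local affine fit, offset ~ a0 + a1*row + a2*col, on the
  // (2*median_win+1)^2 neighborhood of filtered offsets
  const int hw = median_win;
  for (int c = 0; c < cols; ++c) for (int r = 0; r < rows; ++r) {
    if (!keep(r, c)) continue;
    double S = 0, Sr = 0, Sc = 0, Srr = 0, Src = 0, Scc = 0;
    double Tr = 0, Trr = 0, Trc = 0;   // sums of dr target
    double Tc = 0, Tcr = 0, Tcc = 0;   // sums of dc target
    int npts = 0;
    for (int cc = std::max(0, c - hw); cc <= std::min(cols - 1, c + hw); ++cc)
      for (int rr = std::max(0, r - hw); rr <= std::min(rows - 1, r + hw); ++rr) {
        if (!keep(rr, cc)) continue;
        double x = rr - r, y = cc - c;
        double u = fdr(rr, cc), v = fdc(rr, cc);
        S += 1; Sr += x; Sc += y; Srr += x * x; Src += x * y; Scc += y * y;
        Tr += u; Trr += u * x; Trc += u * y;
        Tc += v; Tcr += v * x; Tcc += v * y;
        ++npts;
      }
    if (npts < min_pts) continue;
    // solve the 3x3 normal equations by Cramer's rule
    double det = S * (Srr * Scc - Src * Src) - Sr * (Sr * Scc - Src * Sc) +
      Sc * (Sr * Src - Srr * Sc);
    if (std::fabs(det) < 1e-9) continue;  // degenerate neighborhood
    auto solve = [&](double b0, double b1, double b2, double& a0) {
      // only the intercept (prediction at the centered origin) is needed
      double d0 = b0 * (Srr * Scc - Src * Src) - Sr * (b1 * Scc - Src * b2) +
        Sc * (b1 * Src - Srr * b2);
      a0 = d0 / det;
    };
    double predR, predC;
    solve(Tr, Trr, Trc, predR);
    solve(Tc, Tcr, Tcc, predC);
    double resR = fdr(r, c) - predR, resC = fdc(r, c) - predC;
    if (resR * resR + resC * resC <= thresh) out(r, c) = TRUE;
  }
  return List::create(_["dr"] = fdr, _["dc"] = fdc, _["keep"] = out);
}

static inline double bilin(const NumericMatrix& L, double r, double c) {
  const int rows = L.nrow(), cols = L.ncol();
  if (r < 0) r = 0; if (r > rows - 1) r = rows - 1;
  if (c < 0) c = 0; if (c > cols - 1) c = cols - 1;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = std::min(r0 + 1, rows - 1), c1 = std::min(c0 + 1, cols - 1);
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * L(r0, c0) + fc * L(r0, c1)) +
         fr * ((1 - fc) * L(r1, c0) + fc * L(r1, c1));
}

// Upright SIFT-style descriptors: 16x16 gradient samples spaced by the
// keypoint scale, Gaussian-weighted, soft-binned into 4x4 spatial cells x
// 8 orientation bins; L2-normalized, clipped at 0.2, renormalized.
// `smoothed` holds the per-scale Gaussian-blurred images; `kp` has one row
// per keypoint: (row, col, scale_index [1-based], sigma), coords 0-based.
// [[Rcpp::export]]
NumericMatrix sift_descriptors(List smoothed, NumericMatrix kp) {
  const int n = kp.nrow();
  NumericMatrix out(n, 128);
  for (int i = 0; i < n; ++i) {
    const NumericMatrix L = smoothed[(int)kp(i, 2) - 1];
    const double kr = kp(i, 0), kc = kp(i, 1), sg = kp(i, 3);
    double hist[4][4][8] = {{{0}}};
    for (int a = 0; a < 16; ++a) for (int b = 0; b < 16; ++b) {
      double v = (a - 7.5);     // row offset, sample units
      double u = (b - 7.5);     // col offset, sample units
      double sr = kr + v * sg, sc = kc + u * sg;
      double gy = bilin(L, sr + 1, sc) - bilin(L, sr - 1, sc);
      double gx = bilin(L, sr, sc + 1) - bilin(L, sr, sc - 1);
      double mag = std::sqrt(gx * gx + gy * gy);
      if (mag <= 0) continue;
      double w = std::exp(-(u * u + v * v) / (2.0 * 8.0 * 8.0));
      double th = std::atan2(gy, gx);                 // [-pi, pi]
      double ob = (th + M_PI) / (2.0 * M_PI) * 8.0;   // [0, 8]
      if (ob >= 8.0) ob = 0.0;
      double cr = v / 4.0 + 1.5, cc = u / 4.0 + 1.5;  // cell coords [-0.375, 3.375]
      int cr0 = (int)std::floor(cr), cc0 = (int)std::floor(cc);
      int ob0 = (int)std::floor(ob);
      double fr = cr - cr0, fc = cc - cc0, fo = ob - ob0;
      for (int pr = 0; pr < 2; ++pr) for (int pc = 0; pc < 2; ++pc)
        for (int po = 0; po < 2; ++po) {
          int ir = cr0 + pr, ic = cc0 + pc, io = (ob0 + po) % 8;
          if (ir < 0 || ir > 3 || ic < 0 || ic > 3) continue;
          double wt = w * mag * (pr ? fr : 1 - fr) * (pc ? fc : 1 - fc) *
            (po ? fo : 1 - fo);
          hist[ir][ic][io] += wt;
        }
    }
    double nrm = 0;
    for (int a = 0; a < 4; ++a) for (int b = 0; b < 4; ++b)
      for (int o = 0; o < 8; ++o) nrm += hist[a][b][o] * hist[a][b][o];
    nrm = std::sqrt(nrm);
    if (nrm > 0) {
      double nrm2 = 0;
      for (int a = 0; a < 4; ++a) for (int b = 0; b < 4; ++b)
        for (int o = 0; o < 8; ++o) {
          double x = std::min(hist[a][b][o] / nrm, 0.2);
          hist[a][b][o] = x; nrm2 += x * x;
        }
      nrm2 = std::sqrt(nrm2);
      int k = 0;
      for (int a = 0; a < 4; ++a) for (int b = 0; b < 4; ++b)
        for (int o = 0; o < 8; ++o) out(i, k++) = hist[a][b][o] / nrm2;
    }
  }
  return out;
}
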