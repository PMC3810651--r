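#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// 26-connectivity connected components of a 3D logical array.
// Returns integer labels (0 = background), in array (column-major) order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n, 0);
  int next = 0;
  std::stack<int> todo;
  for (int v = 0; v < n; ++v) {
    if (!mask[v] || labels[v] != 0) continue;
    labels[v] = ++next;
    todo.push(v);
    while (!todo.empty()) {
      int cur = todo.top(); todo.pop();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        int k = ck + dk; if (k < 0 || k >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int j = cj + dj; if (j < 0 || j >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int i = ci + di; if (i < 0 || i >= nx) continue;
            int nb = i + nx * (j + ny * k);
            if (mask[nb] && labels[nb] == 0) {
              labels[nb] = next;
              todo.push(nb);
            }
          }
        }
      }
    }
  }
  return labels;
}

// Max 26-connected cluster size among voxels where supra[v] is true.
static int max_cluster_size(const std::vector<char> &supra, int nx, int ny,
                            int nz, std::vector<int> &visited, int stamp,
                            std::vector<int> &stackBuf) {
  int best = 0;
  const int n = nx * ny * nz;
  for (int v = 0; v < n; ++v) {
    if (!supra[v] || visited[v] == stamp) continue;
    int size = 0;
    stackBuf.clear();
    stackBuf.push_back(v);
    visited[v] = stamp;
    while (!stackBuf.empty()) {
      int cur = stackBuf.back(); stackBuf.pop_back();
      ++size;
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        int k = ck + dk; if (k < 0 || k >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int j = cj + dj; if (j < 0 || j >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int i = ci + di; if (i < 0 || i >= nx) continue;
            int nb = i + nx * (j + ny * k);
            if (supra[nb] && visited[nb] != stamp) {
              visited[nb] = stamp;
              stackBuf.push_back(nb);
            }
          }
        }
      }
    }
    if (size > best) best = size;
  }
  return best;
}

// Foci-relocation permutation null of the maximum supra-threshold cluster
// size. Each permutation relocates every experiment's foci to uniformly
// random in-mask voxel centres (R RNG stream), recomputes the ALE map with
// precomputed voxel-offset kernel cubes (max over an experiment's foci,
// non-additive), thresholds ALE at aleThreshold (strict >), and records the
// maximum 26-connected cluster size.
//
// kernels: list of numeric cubes of side (2*hw+1)^3 (column-major), one per
//   distinct kernel width; kernelIdx maps experiments to kernels (0-based).
// nFoci: per-experiment focus count. maskVox: 0-based in-mask linear
//   indices. Returns the max cluster size per permutation.
// [[Rcpp::export]]
IntegerVector cpp_perm_max_cluster(int nPerm, IntegerVector nFoci,
                                   IntegerVector kernelIdx, List kernels,
                                   IntegerVector halfwidths,
                                   IntegerVector maskVox, IntegerVector dims,
                                   double aleThreshold) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int nExp = nFoci.size();
  const int nMask = maskVox.size();

  std::vector<const double *> kern(kernels.size());
  std::vector<NumericVector> keep;  // keep SEXPs alive
  for (int q = 0; q < kernels.size(); ++q) {
    NumericVector kv = kernels[q];
    keep.push_back(kv);
    kern[q] = REAL(kv);
  }

  std::vector<char> inMask(n, 0);
  for (int m = 0; m < nMask; ++m) inMask[maskVox[m]] = 1;

  std::vector<double> prod(n);
  std::vector<double> ma(n, 0.0);
  std::vector<int> touched; touched.reserve(4096);
  std::vector<char> supra(n, 0);
  std::vector<int> visited(n, 0);
  std::vector<int> stackBuf; stackBuf.reserve(4096);
  IntegerVector out(nPerm);
  RNGScope rng;

  for (int perm = 0; perm < nPerm; ++perm) {
    std::fill(prod.begin(), prod.end(), 1.0);
    for (int e = 0; e < nExp; ++e) {
      const int kq = kernelIdx[e];
      const double *K = kern[kq];
      const int hw = halfwidths[kq];
      const int side = 2 * hw + 1;
      touched.clear();
      for (int f = 0; f < nFoci[e]; ++f) {
        int m = (int)(unif_rand() * nMask);
        if (m >= nMask) m = nMask - 1;
        const int v = maskVox[m];
        const int fi = v % nx, fj = (v / nx) % ny, fk = v / (nx * ny);
        const int i0 = std::max(fi - hw, 0), i1 = std::min(fi + hw, nx - 1);
        const int j0 = std::max(fj - hw, 0), j1 = std::min(fj + hw, ny - 1);
        const int k0 = std::max(fk - hw, 0), k1 = std::min(fk + hw, nz - 1);
        for (int k = k0; k <= k1; ++k) {
          const int kOff = (k - fk + hw) * side * side;
          for (int j = j0; j <= j1; ++j) {
            const int jOff = (j - fj + hw) * side + kOff;
            int vox = i0 + nx * (j + ny * k);
            const double *Krow = K + (i0 - fi + hw) + jOff;
            for (int i = i0; i <= i1; ++i, ++vox, ++Krow) {
              const double val = *Krow;
              if (val > ma[vox]) {
                if (ma[vox] == 0.0) touched.push_back(vox);
                ma[vox] = val;
              }
            }
          }
        }
      }
      for (size_t t = 0; t < touched.size(); ++t) {
        const int vox = touched[t];
        prod[vox] *= (1.0 - ma[vox]);
        ma[vox] = 0.0;
      }
    }
    int nSupra = 0;
    for (int v = 0; v < n; ++v) {
      supra[v] = (inMask[v] && (1.0 - prod[v]) > aleThreshold) ? 1 : 0;
      nSupra += supra[v];
    }
    out[perm] = (nSupra == 0) ? 0
      : max_cluster_size(supra, nx, ny, nz, visited, perm + 1, stackBuf);
  }
  return out;
}

// Combine an ALE-value histogram with one experiment's MA histogram:
// newH[bin(1 - (1-a)(1-m))] += H[a] * p(m), over nonzero bins only.
// hist vectors are dense over bins of width binWidth covering [0, 1].
// [[Rcpp::export]]
NumericVector cpp_combine_hist(NumericVector H, NumericVector maProb,
                               NumericVector maValue, double binWidth) {
  const int nb = H.size();
  NumericVector out(nb);
  const int nm = maProb.size();
  for (int a = 0; a < nb; ++a) {
    const double pa = H[a];
    if (pa <= 0) continue;
    const double av = a * binWidth;
    for (int m = 0; m < nm; ++m) {
      double val = 1.0 - (1.0 - av) * (1.0 - maValue[m]);
      int bin = (int)(val / binWidth + 0.5);  // round: robust to fp error
      if (bin >= nb) bin = nb - 1;
      out[bin] += pa * maProb[m];
    }
  }
  return out;
}
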