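// Gray-level texture-matrix accumulation for 3D masked images.
//
// All functions take a discretized image as an integer vector in R's
// column-major layout with dim (d1, d2, d3); voxels outside the region of
// interest carry level 0 and levels inside run 1..ng. Offsets use the 26
// 3D neighbors; co-occurrence and run-length aggregation uses the 13
// unique (angle-merged) directions, with symmetry handled explicitly.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

static const int DIRS26[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},
  {-1,1,-1},{-1,1,0},{-1,1,1},{0,-1,-1},{0,-1,0},{0,-1,1},
  {0,0,-1},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},{1,-1,-1},
  {1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},{1,1,-1},
  {1,1,0},{1,1,1}
};

// 13 unique directions = the first half of the 26 (each is the negation
// of one in the second half).
static const int NDIR13 = 13;

static inline int idx3(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + d2 * k);
}

static inline bool inb(int i, int j, int k, int d1, int d2, int d3) {
  return i >= 0 && j >= 0 && k >= 0 && i < d1 && j < d2 && k < d3;
}

// [[Rcpp::export(name = ".glcm_counts")]]
NumericMatrix glcm_counts(IntegerVector img, IntegerVector dims, int ng) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericMatrix out(ng, ng);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int g1 = img[idx3(i, j, k, d1, d2)];
        if (g1 <= 0) continue;
        for (int d = 0; d < NDIR13; ++d) {
          int ii = i + DIRS26[d][0], jj = j + DIRS26[d][1], kk = k + DIRS26[d][2];
          if (!inb(ii, jj, kk, d1, d2, d3)) continue;
          int g2 = img[idx3(ii, jj, kk, d1, d2)];
          if (g2 <= 0) continue;
          out(g1 - 1, g2 - 1) += 1.0;
          out(g2 - 1, g1 - 1) += 1.0;  // symmetric co-occurrence
        }
      }
  return out;
}

// [[Rcpp::export(name = ".glrlm_counts")]]
NumericMatrix glrlm_counts(IntegerVector img, IntegerVector dims, int ng) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int maxlen = d1 + d2 + d3;
  NumericMatrix out(ng, maxlen);
  for (int d = 0; d < NDIR13; ++d) {
    int dx = DIRS26[d][0], dy = DIRS26[d][1], dz = DIRS26[d][2];
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          int g = img[idx3(i, j, k, d1, d2)];
          if (g <= 0) continue;
          int pi = i - dx, pj = j - dy, pk = k - dz;
          if (inb(pi, pj, pk, d1, d2, d3) &&
              img[idx3(pi, pj, pk, d1, d2)] == g)
            continue;  // not a run start
          int len = 1;
          int ci = i + dx, cj = j + dy, ck = k + dz;
          while (inb(ci, cj, ck, d1, d2, d3) &&
                 img[idx3(ci, cj, ck, d1, d2)] == g) {
            ++len; ci += dx; cj += dy; ck += dz;
          }
          out(g - 1, len - 1) += 1.0;
        }
  }
  return out;
}

// Zones of 26-connected equal gray level; returns one row per zone:
// (gray level, zone size).
// [[Rcpp::export(name = ".glszm_zones")]]
IntegerMatrix glszm_zones(IntegerVector img, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int n = d1 * d2 * d3;
  std::vector<char> seen(n, 0);
  std::vector<int> glev, gsize;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int start = idx3(i, j, k, d1, d2);
        int g = img[start];
        if (g <= 0 || seen[start]) continue;
        int size = 0;
        std::queue<int> q;
        q.push(start); seen[start] = 1;
        while (!q.empty()) {
          int cur = q.front(); q.pop();
          ++size;
          int ci = cur % d1, cj = (cur / d1) % d2, ck = cur / (d1 * d2);
          for (int d = 0; d < 26; ++d) {
            int ii = ci + DIRS26[d][0], jj = cj + DIRS26[d][1],
                kk = ck + DIRS26[d][2];
            if (!inb(ii, jj, kk, d1, d2, d3)) continue;
            int nb = idx3(ii, jj, kk, d1, d2);
            if (!seen[nb] && img[nb] == g) { seen[nb] = 1; q.push(nb); }
          }
        }
        glev.push_back(g); gsize.push_back(size);
      }
  IntegerMatrix out(glev.size(), 2);
  for (size_t z = 0; z < glev.size(); ++z) {
    out(z, 0) = glev[z]; out(z, 1) = gsize[z];
  }
  return out;
}

// Dependence matrix: for each in-mask voxel with level g, its dependence is
// the number of in-mask 26-neighbors whose level differs by at most alpha;
// counts land in column (dependence + 1).
// [[Rcpp::export(name = ".gldm_counts")]]
NumericMatrix gldm_counts(IntegerVector img, IntegerVector dims, int ng,
                          int alpha) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericMatrix out(ng, 27);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int g = img[idx3(i, j, k, d1, d2)];
        if (g <= 0) continue;
        int dep = 0;
        for (int d = 0; d < 26; ++d) {
          int ii = i + DIRS26[d][0], jj = j + DIRS26[d][1],
              kk = k + DIRS26[d][2];
          if (!inb(ii, jj, kk, d1, d2, d3)) continue;
          int g2 = img[idx3(ii, jj, kk, d1, d2)];
          if (g2 > 0 && std::abs(g2 - g) <= alpha) ++dep;
        }
        out(g - 1, dep) += 1.0;
      }
  return out;
}

// Neighborhood gray-tone difference: per gray level i, n_i = count of
// in-mask voxels of level i having at least one in-mask neighbor, and
// s_i = sum over those voxels of |i - mean neighbor level|.
// [[Rcpp::export(name = ".ngtdm_stats")]]
NumericMatrix ngtdm_stats(IntegerVector img, IntegerVector dims, int ng) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericMatrix out(ng, 2);  // columns: n_i, s_i
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int g = img[idx3(i, j, k, d1, d2)];
        if (g <= 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int d = 0; d < 26; ++d) {
          int ii = i + DIRS26[d][0], jj = j + DIRS26[d][1],
              kk = k + DIRS26[d][2];
          if (!inb(ii, jj, kk, d1, d2, d3)) continue;
          int g2 = img[idx3(ii, jj, kk, d1, d2)];
          if (g2 > 0) { sum += g2; ++cnt; }
        }
        if (cnt > 0) {
          out(g - 1, 0) += 1.0;
          out(g - 1, 1) += std::fabs((double)g - sum / cnt);
        }
      }
  return out;
}
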