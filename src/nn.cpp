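#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Nearest neighbour: for each query row, index (1-based) of the closest
// reference row and the distance. Small reference clouds use brute force;
// larger ones a uniform-grid spatial hash with expanding-ring search.
// [[Rcpp::export]]
List nn_cpp(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  std::vector<double> rx(m), ry(m), rz(m);
  for (int j = 0; j < m; ++j) { rx[j] = ref(j,0); ry[j] = ref(j,1); rz[j] = ref(j,2); }
  if (m <= 1500) {
    for (int i = 0; i < n; ++i) {
      double qx = query(i,0), qy = query(i,1), qz = query(i,2);
      double best = R_PosInf; int bj = -1;
      for (int j = 0; j < m; ++j) {
        double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best) { best = d2; bj = j; }
      }
      idx[i] = bj + 1;
      dist[i] = std::sqrt(best);
    }
    return List::create(_["idx"] = idx, _["dist"] = dist);
  }
  // uniform grid over the reference bounding box, ~4 points per cell
  double lo[3] = {rx[0], ry[0], rz[0]}, hi[3] = {rx[0], ry[0], rz[0]};
  for (int j = 0; j < m; ++j) {
    lo[0] = std::min(lo[0], rx[j]); hi[0] = std::max(hi[0], rx[j]);
    lo[1] = std::min(lo[1], ry[j]); hi[1] = std::max(hi[1], ry[j]);
    lo[2] = std::min(lo[2], rz[j]); hi[2] = std::max(hi[2], rz[j]);
  }
  double ext[3], maxext = 1e-12;
  for (int a = 0; a < 3; ++a) {
    ext[a] = hi[a] - lo[a];
    maxext = std::max(maxext, ext[a]);
  }
  double cell = std::cbrt(std::max(ext[0], 1e-9) * std::max(ext[1], 1e-9) *
                          std::max(ext[2], 1e-9) / (m / 4.0));
  if (!(cell > 0) || cell < maxext / 128.0) cell = maxext / 128.0;
  int dims[3];
  for (int a = 0; a < 3; ++a)
    dims[a] = std::max(1, std::min(128, (int)(ext[a] / cell) + 1));
  const int ncell = dims[0] * dims[1] * dims[2];
  std::vector<int> count(ncell + 1, 0), cellof(m);
  auto cell_of = [&](double x, double y, double z) {
    int cx = std::min(dims[0]-1, std::max(0, (int)((x - lo[0]) / cell)));
    int cy = std::min(dims[1]-1, std::max(0, (int)((y - lo[1]) / cell)));
    int cz = std::min(dims[2]-1, std::max(0, (int)((z - lo[2]) / cell)));
    return (cz * dims[1] + cy) * dims[0] + cx;
  };
  for (int j = 0; j < m; ++j) { cellof[j] = cell_of(rx[j], ry[j], rz[j]); count[cellof[j] + 1]++; }
  for (int c = 0; c < ncell; ++c) count[c + 1] += count[c];
  std::vector<int> bucket(m);
  { std::vector<int> fill(count.begin(), count.end() - 1);
    for (int j = 0; j < m; ++j) bucket[fill[cellof[j]]++] = j; }
  for (int i = 0; i < n; ++i) {
    double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    int cx = std::min(dims[0]-1, std::max(0, (int)((qx - lo[0]) / cell)));
    int cy = std::min(dims[1]-1, std::max(0, (int)((qy - lo[1]) / cell)));
    int cz = std::min(dims[2]-1, std::max(0, (int)((qz - lo[2]) / cell)));
    double best = R_PosInf; int bj = -1;
    int maxr = std::max(dims[0], std::max(dims[1], dims[2]));
    for (int r = 0; r <= maxr; ++r) {
      // once a hit exists, stop when the ring cannot contain anything closer
      if (bj >= 0) {
        double ring_lb = (r - 1) * cell;  // conservative lower bound
        if (ring_lb > 0 && ring_lb * ring_lb > best) break;
      }
      for (int dz = -r; dz <= r; ++dz) {
        int z = cz + dz; if (z < 0 || z >= dims[2]) continue;
        for (int dy = -r; dy <= r; ++dy) {
          int y = cy + dy; if (y < 0 || y >= dims[1]) continue;
          for (int dx = -r; dx <= r; ++dx) {
            // only the shell of the ring
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;
            int x = cx + dx; if (x < 0 || x >= dims[0]) continue;
            int c = (z * dims[1] + y) * dims[0] + x;
            for (int kk = count[c]; kk < count[c + 1]; ++kk) {
              int j = bucket[kk];
              double ddx = qx - rx[j], ddy = qy - ry[j], ddz = qz - rz[j];
              double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
              if (d2 < best) { best = d2; bj = j; }
            }
          }
        }
      }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// k nearest neighbours, ties broken by lower reference index.
// [[Rcpp::export]]
List knn_cpp(NumericMatrix query, NumericMatrix ref, int k) {
  const int n = query.nrow(), m = ref.nrow();
  if (k > m) stop("knn_cpp: k exceeds number of reference points");
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<std::pair<double,int> > d2(m);
  for (int i = 0; i < n; ++i) {
    double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    for (int j = 0; j < m; ++j) {
      double dx = qx - ref(j,0), dy = qy - ref(j,1), dz = qz - ref(j,2);
      d2[j] = std::make_pair(dx*dx + dy*dy + dz*dz, j);
    }
    std::partial_sort(d2.begin(), d2.begin() + k, d2.end());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = d2[j].second + 1;
      dist(i, j) = std::sqrt(d2[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
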