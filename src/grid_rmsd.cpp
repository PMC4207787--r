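// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>

using namespace Rcpp;

// Optimal proper rotation (Kabsch) mapping centered mobile B onto centered
// reference A; returns RMSD of (sel_mobile rotated) vs sel_ref.
// sup_*: m_sup x 3 centered superposition coordinates
// sel_*: m_sel x 3 coordinates, already centered on the sup centroids
static double kabsch_rmsd(const arma::mat& sup_ref, const arma::mat& sup_mob,
                          const arma::mat& sel_ref, const arma::mat& sel_mob) {
  arma::mat H = sup_mob.t() * sup_ref;  // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  arma::mat R = U * D * V.t();  // rotation for row vectors: x_new = x * R
  arma::mat diff = sel_mob * R - sel_ref;
  return std::sqrt(arma::accu(diff % diff) / diff.n_rows);
}

// Pairwise superposed-RMSD matrix over an ensemble.
// sup: m_sup x 3 x n cube (superposition selection coordinates per frame)
// sel: m_sel x 3 x n cube (measurement selection coordinates per frame)
// Entry (i,j), i < j: frame j superposed onto frame i over sup, RMSD over sel;
// mirrored to the lower triangle.
// [[Rcpp::export]]
NumericMatrix pairwise_rmsd_cpp(arma::cube sup, arma::cube sel) {
  const int n = sup.n_slices;
  NumericMatrix out(n, n);
  std::vector<arma::mat> sup_c(n), sel_c(n);
  for (int i = 0; i < n; ++i) {
    arma::mat S = sup.slice(i);
    arma::rowvec c = arma::mean(S, 0);
    sup_c[i] = S.each_row() - c;
    arma::mat M = sel.slice(i);
    sel_c[i] = M.each_row() - c;
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double r = kabsch_rmsd(sup_c[i], sup_c[j], sel_c[i], sel_c[j]);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Burial count per grid cell: for each of the 26 lattice directions, a cell
// counts as blocked if any protein cell lies on the ray from it in that
// direction. Single sweep per direction via the recurrence
//   blocked(c) = protein(c + d) | blocked(c + d),
// processing cells in an order where c + d is always visited first.
// [[Rcpp::export]]
IntegerVector burial_count_cpp(LogicalVector protein, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector count(n, 0);
  std::vector<char> blocked(n);
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        std::fill(blocked.begin(), blocked.end(), 0);
        // iterate against the direction so that (x+dx, y+dy, z+dz) is done
        const int x0 = dx > 0 ? nx - 1 : 0, x1 = dx > 0 ? -1 : nx,
                  xs = dx > 0 ? -1 : 1;
        const int y0 = dy > 0 ? ny - 1 : 0, y1 = dy > 0 ? -1 : ny,
                  ys = dy > 0 ? -1 : 1;
        const int z0 = dz > 0 ? nz - 1 : 0, z1 = dz > 0 ? -1 : nz,
                  zs = dz > 0 ? -1 : 1;
        for (int z = z0; z != z1; z += zs)
          for (int y = y0; y != y1; y += ys)
            for (int x = x0; x != x1; x += xs) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              char b = 0;
              if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 &&
                  zz < nz) {
                int k = idx3(xx, yy, zz, nx, ny);
                b = (protein[k] || blocked[k]) ? 1 : 0;
              }
              int c = idx3(x, y, z, nx, ny);
              blocked[c] = b;
              if (b) count[c] += 1;
            }
      }
  return count;
}

// Multi-source BFS (6-neighbourhood) from "open" cells through non-protein
// cells; returns step counts (-1 = unreachable). Used for pocket depth.
// [[Rcpp::export]]
IntegerVector grid_depth_cpp(LogicalVector protein, LogicalVector open,
                             IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector dist(n, -1);
  std::queue<int> q;
  for (int i = 0; i < n; ++i)
    if (open[i] && !protein[i]) {
      dist[i] = 0;
      q.push(i);
    }
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    int c = q.front();
    q.pop();
    int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
    for (int k = 0; k < 6; ++k) {
      int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int cc = idx3(xx, yy, zz, nx, ny);
      if (!protein[cc] && dist[cc] < 0) {
        dist[cc] = dist[c] + 1;
        q.push(cc);
      }
    }
  }
  return dist;
}
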