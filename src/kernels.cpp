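#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Accumulate element stiffness contributions into the numeric slot of the
// preassembled sparse pattern.  For voxel hexahedra with isotropic material
// the element matrix separates as ke = lambda * Kl + mu * Km, with Kl, Km
// depending only on the voxel edge length.  trip_* are parallel arrays over
// the kept (free x free, upper-triangle) triplets.
// [[Rcpp::export]]
NumericVector cpp_fill_stiffness(NumericVector Kl, NumericVector Km,
                                 NumericVector lambda, NumericVector mu,
                                 IntegerVector trip_e, IntegerVector trip_k,
                                 IntegerVector trip_pos, int nnz) {
  NumericVector x(nnz);
  const int nt = trip_e.size();
  for (int t = 0; t < nt; ++t) {
    const int e = trip_e[t];
    const int k = trip_k[t];
    x[trip_pos[t]] += lambda[e] * Kl[k] + mu[e] * Km[k];
  }
  return x;
}

// Centroid small-strain tensor per element: eps = B0 %*% u[edof].
// edof is nel x 24 with 1-based global dof indices; rows of the result are
// (e_xx, e_yy, e_zz, g_xy, g_yz, g_zx) with engineering shear components.
// [[Rcpp::export]]
NumericMatrix cpp_cell_strains(NumericMatrix B0, NumericVector u,
                               IntegerMatrix edof) {
  const int nel = edof.nrow();
  NumericMatrix eps(nel, 6);
  double ue[24];
  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < 24; ++a) ue[a] = u[edof(e, a) - 1];
    for (int r = 0; r < 6; ++r) {
      double s = 0.0;
      for (int a = 0; a < 24; ++a) s += B0(r, a) * ue[a];
      eps(e, r) = s;
    }
  }
  return eps;
}

static inline bool in_grid(int i, int j, int k, int nx, int ny, int nz) {
  return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
}

// Breadth-first path search on the cell lattice: is any seed cell connected
// to any target cell through passable cells?  conn26 switches from face (6)
// to full (26) connectivity.
// [[Rcpp::export]]
bool cpp_path_connected(IntegerVector dims, LogicalVector pass,
                        IntegerVector seeds, IntegerVector targets,
                        bool conn26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> visited(n, 0), is_target(n, 0);
  for (int t = 0; t < targets.size(); ++t) is_target[targets[t] - 1] = 1;
  std::queue<int> q;
  for (int s = 0; s < seeds.size(); ++s) {
    int c = seeds[s] - 1;
    if (c >= 0 && c < n && pass[c] && !visited[c]) {
      if (is_target[c]) return true;
      visited[c] = 1;
      q.push(c);
    }
  }
  while (!q.empty()) {
    int c = q.front(); q.pop();
    int i = c % nx, j = (c / nx) % ny, k = c / (nx * ny);
    int lo = conn26 ? -1 : 0;
    if (conn26) {
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (!in_grid(ii, jj, kk, nx, ny, nz)) continue;
            int cc = ii + nx * (jj + ny * kk);
            if (!pass[cc] || visited[cc]) continue;
            if (is_target[cc]) return true;
            visited[cc] = 1;
            q.push(cc);
          }
    } else {
      const int di[6] = {1, -1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, 1, -1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, 1, -1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (!in_grid(ii, jj, kk, nx, ny, nz)) continue;
        int cc = ii + nx * (jj + ny * kk);
        if (!pass[cc] || visited[cc]) continue;
        if (is_target[cc]) return true;
        visited[cc] = 1;
        q.push(cc);
      }
    }
    (void)lo;
  }
  return false;
}

// Face-connected component labels over active cells (0 for inactive cells,
// components numbered from 1).  Used for singular-system diagnostics.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector dims, LogicalVector active) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  int next = 0;
  std::queue<int> q;
  for (int c0 = 0; c0 < n; ++c0) {
    if (!active[c0] || lab[c0]) continue;
    lab[c0] = ++next;
    q.push(c0);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int i = c % nx, j = (c / nx) % ny, k = c / (nx * ny);
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (!in_grid(ii, jj, kk, nx, ny, nz)) continue;
        int cc = ii + nx * (jj + ny * kk);
        if (active[cc] && !lab[cc]) { lab[cc] = next; q.push(cc); }
      }
    }
  }
  return lab;
}
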