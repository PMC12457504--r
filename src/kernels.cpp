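// Numerical kernels: exact signed distance to inter-voxel phase faces,
// 3D connected components, separable Gaussian smoothing, XFEM element
// integration, spectral pseudo-inverse blocks, Bond rotation of stiffness,
// and homogenization accumulators.
#include <RcppArmadillo.h>
#include <vector>
#include <array>
#include <cmath>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline long IDX(int i, int j, int k, int nx, int ny) {
  return (long)i + (long)nx * ((long)j + (long)ny * k);
}

struct Face {
  // axis: 0,1,2 = face normal along x,y,z; center coordinates in physical units
  unsigned char axis;
  double cx, cy, cz;
};

// Exact signed Euclidean distance from each voxel center to the closest
// point on the solid/void interface, where the interface is the set of
// rectangular faces between voxels of opposite phase. Positive in solid.
// [[Rcpp::export]]
NumericVector cpp_signed_face_distance(LogicalVector solid, IntegerVector dims,
                                       NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const long n = (long)nx * ny * nz;
  const double hmin = std::min(hx, std::min(hy, hz));
  const double step = std::sqrt(hx * hx + hy * hy + hz * hz);

  // bucket faces by the lower adjacent voxel cell
  std::vector<std::vector<Face>> buckets(n);
  long nfaces = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long id = IDX(i, j, k, nx, ny);
        bool s = solid[id];
        if (i + 1 < nx && s != (bool)solid[IDX(i + 1, j, k, nx, ny)]) {
          buckets[id].push_back({0, (i + 1.0) * hx, (j + 0.5) * hy, (k + 0.5) * hz});
          ++nfaces;
        }
        if (j + 1 < ny && s != (bool)solid[IDX(i, j + 1, k, nx, ny)]) {
          buckets[id].push_back({1, (i + 0.5) * hx, (j + 1.0) * hy, (k + 0.5) * hz});
          ++nfaces;
        }
        if (k + 1 < nz && s != (bool)solid[IDX(i, j, k + 1, nx, ny)]) {
          buckets[id].push_back({2, (i + 0.5) * hx, (j + 0.5) * hy, (k + 1.0) * hz});
          ++nfaces;
        }
      }
  if (nfaces == 0) stop("no phase boundary exists");

  NumericVector phi(n);
  const int rmax = std::max(nx, std::max(ny, nz));
  std::vector<double> dist(n, -1.0);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const long id = IDX(i, j, k, nx, ny);
        const double px = (i + 0.5) * hx, py = (j + 0.5) * hy, pz = (k + 0.5) * hz;
        // warm start: distance is 1-Lipschitz between neighboring centers
        double best = std::numeric_limits<double>::infinity();
        if (i > 0 && dist[IDX(i - 1, j, k, nx, ny)] >= 0)
          best = std::min(best, dist[IDX(i - 1, j, k, nx, ny)] + hx);
        if (j > 0 && dist[IDX(i, j - 1, k, nx, ny)] >= 0)
          best = std::min(best, dist[IDX(i, j - 1, k, nx, ny)] + hy);
        if (k > 0 && dist[IDX(i, j, k - 1, nx, ny)] >= 0)
          best = std::min(best, dist[IDX(i, j, k - 1, nx, ny)] + hz);

        for (int r = 0; r <= rmax; ++r) {
          if (r >= 1 && (r - 0.5) * hmin > best) break;
          const int i0 = std::max(0, i - r), i1 = std::min(nx - 1, i + r);
          const int j0 = std::max(0, j - r), j1 = std::min(ny - 1, j + r);
          const int k0 = std::max(0, k - r), k1 = std::min(nz - 1, k + r);
          for (int kk = k0; kk <= k1; ++kk)
            for (int jj = j0; jj <= j1; ++jj)
              for (int ii = i0; ii <= i1; ++ii) {
                // shell membership (Chebyshev radius exactly r)
                int cr = std::max(std::abs(ii - i),
                                  std::max(std::abs(jj - j), std::abs(kk - k)));
                if (cr != r) continue;
                const std::vector<Face> &fv = buckets[IDX(ii, jj, kk, nx, ny)];
                for (size_t f = 0; f < fv.size(); ++f) {
                  const Face &F = fv[f];
                  double dx, dy, dz;
                  if (F.axis == 0) {
                    dx = px - F.cx;
                    dy = std::max(0.0, std::fabs(py - F.cy) - 0.5 * hy);
                    dz = std::max(0.0, std::fabs(pz - F.cz) - 0.5 * hz);
                  } else if (F.axis == 1) {
                    dx = std::max(0.0, std::fabs(px - F.cx) - 0.5 * hx);
                    dy = py - F.cy;
                    dz = std::max(0.0, std::fabs(pz - F.cz) - 0.5 * hz);
                  } else {
                    dx = std::max(0.0, std::fabs(px - F.cx) - 0.5 * hx);
                    dy = std::max(0.0, std::fabs(py - F.cy) - 0.5 * hy);
                    dz = pz - F.cz;
                  }
                  double d = std::sqrt(dx * dx + dy * dy + dz * dz);
                  if (d < best) best = d;
                }
              }
        }
        dist[id] = best;
        phi[id] = solid[id] ? best : -best;
        (void)step;
      }
  return phi;
}

// 26- or 6-connected component labeling of a binary mask (BFS).
// Returns integer labels, 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      long cur = stack.back();
      stack.pop_back();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((long)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 &&
                std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
              continue;
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            long nb = IDX(ii, jj, kk, nx, ny);
            if (mask[nb] && lab[nb] == 0) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
    }
  }
  return lab;
}

// Separable Gaussian smoothing with replicated boundary.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3(NumericVector vol, IntegerVector dims,
                                 double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + rad];
  }
  for (auto &v : ker) v /= s;

  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int N[3] = {nx, ny, nz};
  const long stride[3] = {1, nx, (long)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long id = IDX(i, j, k, nx, ny);
          int pos = (ax == 0) ? i : (ax == 1 ? j : k);
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int p = pos + t;
            if (p < 0) p = 0;
            if (p >= N[ax]) p = N[ax] - 1;
            acc += ker[t + rad] * a[id + (long)(p - pos) * stride[ax]];
          }
          b[id] = acc;
        }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Element integration: K^e = sum_q w_q B_q^T C B_q, F^e = sum_q w_q B_q^T C,
// f^e = sum_q w_q B_q^T C beta (weights w_q already include det J).
// B: 6 x 24 x nq cube shared by all elements (axis-aligned identical cells),
// Cmats: 36 x ne, betav: 6 x ne, wdet: nq x ne, conn: 24 x ne 1-based dof ids.
// Scatters F and f into dense global arrays; returns vectorized K^e blocks.
// [[Rcpp::export]]
List cpp_element_system(const arma::cube &B, const arma::mat &Cmats,
                        const arma::mat &betav, const arma::mat &wdet,
                        const IntegerMatrix &conn, int ndof) {
  const int nq = B.n_slices, ne = Cmats.n_cols;
  arma::mat Kel(576, ne);
  arma::mat Fglob(ndof, 6, arma::fill::zeros);
  arma::vec fglob(ndof, arma::fill::zeros);
  arma::mat Ke(24, 24), Fe(24, 6), C(6, 6);
  arma::vec fe(24), beta(6);
  for (int e = 0; e < ne; ++e) {
    C = arma::reshape(Cmats.col(e), 6, 6);
    beta = betav.col(e);
    Ke.zeros();
    Fe.zeros();
    fe.zeros();
    for (int q = 0; q < nq; ++q) {
      double w = wdet(q, e);
      if (w == 0.0) continue;
      const arma::mat &Bq = B.slice(q);
      arma::mat CB = C * Bq;            // 6 x 24
      Ke += w * (Bq.t() * CB);
      Fe += w * (Bq.t() * C);
      fe += w * (Bq.t() * (C * beta));
    }
    if (!Ke.is_finite()) stop("non-finite element contribution at element %d", e + 1);
    Kel.col(e) = arma::vectorise(Ke);
    for (int a = 0; a < 24; ++a) {
      int d = conn(a, e) - 1;
      for (int j = 0; j < 6; ++j) Fglob(d, j) += Fe(a, j);
      fglob(d) += fe(a);
    }
  }
  return List::create(_["Kel"] = Kel, _["F"] = Fglob, _["f"] = fglob);
}

// Spectral pseudo-inverse of each 24x24 element stiffness block,
// zeroing eigenvalues <= eps * max(lambda) (per element).
// [[Rcpp::export]]
arma::mat cpp_pinv_blocks(const arma::mat &Kel, double eps) {
  const int ne = Kel.n_cols;
  arma::mat out(576, ne);
  arma::mat Ke(24, 24), V;
  arma::vec lam;
  for (int e = 0; e < ne; ++e) {
    Ke = arma::reshape(Kel.col(e), 24, 24);
    Ke = 0.5 * (Ke + Ke.t());
    arma::eig_sym(lam, V, Ke);
    double lmax = lam.max();
    double lth = eps * std::max(lmax, 0.0);
    arma::vec li(24, arma::fill::zeros);
    for (int i = 0; i < 24; ++i)
      if (lam(i) > lth) li(i) = 1.0 / lam(i);
    out.col(e) = arma::vectorise(V * arma::diagmat(li) * V.t());
  }
  return out;
}

static void bond_matrix(const arma::mat &R, arma::mat &M) {
  // stress transformation sigma_global = M sigma_local for Voigt order
  // (11,22,33,23,13,12), R columns = global components of local axes.
  auto a = [&R](int p, int i) { return R(p, i); };
  int pair1[3] = {1, 0, 0}, pair2[3] = {2, 2, 1};  // Voigt 4,5,6 -> (2,3),(1,3),(1,2)
  for (int p = 0; p < 3; ++p) {
    for (int q = 0; q < 3; ++q) M(p, q) = a(p, q) * a(p, q);
    for (int q = 0; q < 3; ++q) {
      int i = pair1[q], j = pair2[q];
      M(p, 3 + q) = 2.0 * a(p, i) * a(p, j);
    }
  }
  for (int r = 0; r < 3; ++r) {
    int p = pair1[r], q = pair2[r];
    for (int c = 0; c < 3; ++c) M(3 + r, c) = a(p, c) * a(q, c);
    for (int c = 0; c < 3; ++c) {
      int i = pair1[c], j = pair2[c];
      M(3 + r, 3 + c) = a(p, i) * a(q, j) + a(p, j) * a(q, i);
    }
  }
}

// Rotate local orthotropic stiffness/expansion into the global frame.
// type: 1 = axial (rotation about z, local 3 -> z), 2 = ray (rotation about
// x, local 3 -> x). alpha in radians. Returns 36 x ne and 6 x ne matrices.
// [[Rcpp::export]]
List cpp_rotate_materials(const arma::mat &Cax, const arma::vec &bax,
                          const arma::mat &Cray, const arma::vec &bray,
                          const NumericVector &alpha,
                          const IntegerVector &type) {
  const int ne = alpha.size();
  arma::mat Cout(36, ne), bout(6, ne);
  arma::mat R(3, 3), M(6, 6), Cg(6, 6), Bt(3, 3);
  for (int e = 0; e < ne; ++e) {
    double ca = std::cos(alpha[e]), sa = std::sin(alpha[e]);
    const arma::mat &Cl = (type[e] == 2) ? Cray : Cax;
    const arma::vec &bl = (type[e] == 2) ? bray : bax;
    if (type[e] == 2) {
      // local1=(0,ca,sa), local2=(0,-sa,ca), local3=(1,0,0)
      R = {{0.0, 0.0, 1.0}, {ca, -sa, 0.0}, {sa, ca, 0.0}};
    } else {
      // local1=(ca,sa,0), local2=(-sa,ca,0), local3=(0,0,1)
      R = {{ca, -sa, 0.0}, {sa, ca, 0.0}, {0.0, 0.0, 1.0}};
    }
    bond_matrix(R, M);
    Cg = M * Cl * M.t();
    Cout.col(e) = arma::vectorise(Cg);
    Bt = R * arma::diagmat(bl) * R.t();
    bout(0, e) = Bt(0, 0);
    bout(1, e) = Bt(1, 1);
    bout(2, e) = Bt(2, 2);
    bout(3, e) = 2.0 * Bt(1, 2);
    bout(4, e) = 2.0 * Bt(0, 2);
    bout(5, e) = 2.0 * Bt(0, 1);
  }
  return List::create(_["C"] = Cout, _["beta"] = bout);
}

// Accumulate the homogenized stiffness and hygric load:
//   Cbar_sum = sum_e sum_q w C (B u_mech + I6)
//   rbeta_sum = sum_e sum_q w C (beta - B u_hyg)
// U: ndof x 7 (6 mechanical columns + 1 hygric).
// [[Rcpp::export]]
List cpp_homogenize_accum(const arma::cube &B, const arma::mat &Cmats,
                          const arma::mat &betav, const arma::mat &wdet,
                          const IntegerMatrix &conn, const arma::mat &U) {
  const int nq = B.n_slices, ne = Cmats.n_cols;
  arma::mat Cbar(6, 6, arma::fill::zeros);
  arma::vec rb(6, arma::fill::zeros);
  arma::mat ue(24, 7), C(6, 6);
  arma::mat I6(6, 6, arma::fill::eye);
  for (int e = 0; e < ne; ++e) {
    C = arma::reshape(Cmats.col(e), 6, 6);
    for (int a = 0; a < 24; ++a) {
      int d = conn(a, e) - 1;
      for (int j = 0; j < 7; ++j) ue(a, j) = U(d, j);
    }
    for (int q = 0; q < nq; ++q) {
      double w = wdet(q, e);
      if (w == 0.0) continue;
      const arma::mat &Bq = B.slice(q);
      arma::mat G = Bq * ue;  // 6 x 7
      Cbar += w * (C * (G.cols(0, 5) + I6));
      rb += w * (C * (betav.col(e) - G.col(6)));
    }
  }
  return List::create(_["Cbar_sum"] = Cbar, _["rbeta_sum"] = rb);
}
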